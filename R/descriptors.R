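# 2D descriptors feeding the SVM filter: the Kier alpha-modified second
# shape index (KierA2) and SlogP_VSA1, the van der Waals surface area summed
# over atoms whose atomic logP contribution falls in (-0.4, -0.2].

# Hall-Kier alpha contributions (covalent-radius correction relative to sp3
# carbon) by element and hybridisation. Aromatic atoms take the sp2 value.
.HALL_KIER_ALPHA <- list(
  C = c(SP3 = 0.00, SP2 = -0.13, SP = -0.22),
  N = c(SP3 = -0.04, SP2 = -0.20, SP = -0.29),
  O = c(SP3 = -0.04, SP2 = -0.20),
  S = c(SP3 = 0.35, SP2 = 0.22),
  P = c(SP3 = 0.43),
  F = c(SP3 = -0.07, SP2 = -0.07),
  Cl = c(SP3 = 0.29),
  Br = c(SP3 = 0.48),
  I = c(SP3 = 0.73)
)

.resolve_graph <- function(molecule) {
  if (inherits(molecule, "mol_graph")) return(molecule)
  if (is.character(molecule) && length(molecule) == 1) {
    g <- mol_graphs(molecule)[[1]]
    if (is.null(g)) stop("unparsable SMILES: '", molecule, "'")
    return(g)
  }
  stop("molecule must be a SMILES string or a mol_graph")
}

.alpha_sum <- function(graph) {
  sum(vapply(seq_len(nrow(graph$atoms)), function(i) {
    a <- graph$atoms[i, ]
    tab <- .HALL_KIER_ALPHA[[a$element]]
    if (is.null(tab)) {
      stop("no Hall-Kier alpha parameter for element ", a$element)
    }
    hyb <- if (isTRUE(a$aromatic)) "SP2" else a$hyb
    if (!hyb %in% names(tab)) hyb <- names(tab)[1]
    unname(tab[hyb])
  }, numeric(1)))
}

.path2_count <- function(graph) {
  # every 2-bond path has a unique central atom: P2 = sum choose(deg, 2)
  deg <- integer(graph$n_heavy)
  if (nrow(graph$bonds) > 0) {
    tab <- table(c(graph$bonds$i, graph$bonds$j))
    deg[as.integer(names(tab))] <- as.integer(tab)
  }
  sum(choose(deg, 2))
}

#' Kier alpha-modified second shape index (KierA2)
#'
#' `(A + alpha - 1) (A + alpha - 2)^2 / (P2 + alpha)^2` where `A` is the
#' heavy-atom count, `P2` the number of 2-bond paths and `alpha` the sum of
#' Hall-Kier covalent-radius corrections relative to sp3 carbon. For an
#' unbranched chain of A identical sp3 atoms the index equals `A - 1`.
#'
#' @param molecule SMILES string or `mol_graph`.
#' @return dimensionless shape index.
#' @export
kier_alpha2 <- function(molecule) {
  g <- .resolve_graph(molecule)
  A <- g$n_heavy
  P2 <- .path2_count(g)
  if (A < 3 || P2 < 1) {
    stop("KierA2 undefined for molecules with fewer than 3 heavy atoms")
  }
  alpha <- .alpha_sum(g)
  (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
}

# ---- SlogP_VSA1 -----------------------------------------------------------

# "moe" parameterisation: per-atom-class constants reverse-engineered from
# the printed descriptor table of the reference campaign, where the only
# atom classes with logP contribution inside (-0.4, -0.2] are the
# ester/carboxylic oxygen (VSA 7.7454643), the ketone oxygen (5.6876111)
# and the amide group (5.2587838). Alcohol, aldehyde, ether/epoxide oxygens
# and nitrile nitrogens fall outside the bin and contribute 0.
.MOE_VSA_ESTER <- 7.7454643
.MOE_VSA_KETONE <- 5.6876111
.MOE_VSA_AMIDE <- 5.2587838

.neighbours <- function(graph, i) {
  b <- graph$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

.bond_order <- function(graph, i, j) {
  b <- graph$bonds
  sel <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
  if (!any(sel)) return(0)
  b$order[sel][1]
}

.slogp_vsa1_moe <- function(graph) {
  at <- graph$atoms
  total <- 0
  # iterate over carbonyl carbons and classify the C=O group
  for (i in seq_len(nrow(at))) {
    if (at$element[i] != "C") next
    nb <- .neighbours(graph, i)
    dbl_o <- nb[at$element[nb] == "O" &
                  vapply(nb, function(j) .bond_order(graph, i, j) == 2,
                         logical(1))]
    if (length(dbl_o) == 0) next
    sgl_o <- nb[at$element[nb] == "O" &
                  vapply(nb, function(j) .bond_order(graph, i, j) == 1,
                         logical(1))]
    sgl_n <- nb[at$element[nb] == "N"]
    c_nb <- nb[at$element[nb] == "C"]
    if (length(sgl_o) > 0) {
      total <- total + .MOE_VSA_ESTER        # ester, lactone or acid
    } else if (length(sgl_n) > 0) {
      total <- total + .MOE_VSA_AMIDE        # amide
    } else if (length(c_nb) == 2) {
      total <- total + .MOE_VSA_KETONE       # ketone
    }
    # aldehydes (one C neighbour, no O/N single bond) are outside the bin
  }
  total
}

.slogp_vsa1_crippen <- function(graph) {
  lp <- graph$atoms$crippen_logp
  sum(graph$atoms$vsa[lp > -0.4 & lp <= -0.2])
}

#' SlogP_VSA1: surface area of mildly hydrophilic atoms
#'
#' Sum of approximate per-atom van der Waals surface area over atoms whose
#' atomic logP contribution lies in the half-open bin (-0.4, -0.2].
#'
#' Two parameterisations are provided. `"moe"` (default) reproduces the
#' descriptor convention of the reference campaign, under which ester /
#' carboxylic-acid groups contribute 7.7454643, ketone oxygens 5.6876111 and
#' amides 5.2587838, while alcohol, aldehyde, ether and nitrile heteroatoms
#' fall outside the bin. `"crippen"` uses the published Wildman-Crippen
#' atomic contributions with Labute per-atom surface areas; the two differ
#' for alcohols and aldehydes (see the methods vignette).
#'
#' @param molecule SMILES string or `mol_graph`.
#' @param params `"moe"` or `"crippen"`.
#' @return surface area in square Angstrom (0 when no atom is in the bin).
#' @export
slogp_vsa1 <- function(molecule, params = c("moe", "crippen")) {
  params <- match.arg(params)
  g <- .resolve_graph(molecule)
  switch(params,
         moe = .slogp_vsa1_moe(g),
         crippen = .slogp_vsa1_crippen(g))
}

#' Descriptor matrix for a set of compounds
#'
#' @param compounds data.frame with `compound_id` and `smiles`, or a
#'   character vector of SMILES (ids default to the SMILES).
#' @param descriptors descriptor names; built-ins are `"kier_a2"` and
#'   `"slogp_vsa1"`; additionally any name in `extras`.
#' @param params SlogP_VSA1 parameterisation, see [slogp_vsa1()].
#' @param extras optional named list of functions `f(mol_graph) -> numeric`
#'   providing further 2D descriptors (used by the descriptor-pair search).
#' @return data.frame: `compound_id` plus one numeric column per descriptor.
#'   Errors aggregate: if any compound fails, the whole call fails with a
#'   message naming each offender.
#' @export
descriptor_matrix <- function(compounds,
                              descriptors = c("kier_a2", "slogp_vsa1"),
                              params = "moe", extras = list()) {
  if (is.character(compounds)) {
    compounds <- data.frame(compound_id = compounds, smiles = compounds,
                            stringsAsFactors = FALSE)
  }
  if (NROW(compounds) == 0) stop("empty compound list")
  if (any(is.na(compounds$smiles))) {
    stop("compounds without structures: ",
         paste(compounds$compound_id[is.na(compounds$smiles)],
               collapse = ", "))
  }
  graphs <- mol_graphs(compounds$smiles)
  fns <- list(
    kier_a2 = kier_alpha2,
    slogp_vsa1 = function(g) slogp_vsa1(g, params = params)
  )
  fns <- c(fns, extras)
  unknown <- setdiff(descriptors, names(fns))
  if (length(unknown) > 0) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "))
  }
  errors <- character(0)
  vals <- matrix(NA_real_, NROW(compounds), length(descriptors),
                 dimnames = list(NULL, descriptors))
  for (i in seq_len(NROW(compounds))) {
    if (is.null(graphs[[i]])) {
      errors <- c(errors, paste0(compounds$compound_id[i],
                                 ": unparsable SMILES"))
      next
    }
    for (d in descriptors) {
      v <- tryCatch(fns[[d]](graphs[[i]]), error = function(e) {
        errors <<- c(errors, paste0(compounds$compound_id[i], " [", d, "]: ",
                                    conditionMessage(e)))
        NA_real_
      })
      vals[i, d] <- v
    }
  }
  if (length(errors) > 0) {
    stop("descriptor computation failed for:\n  ",
         paste(errors, collapse = "\n  "))
  }
  cbind(data.frame(compound_id = compounds$compound_id,
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}
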