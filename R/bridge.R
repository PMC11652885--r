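# Thin system-RDKit bridge. Everything chemical-format related (SMILES/SDF
# parsing, 3D embedding, Crippen atomic parameters) is delegated to RDKit
# through one python helper script; all downstream science is R code.

.bridge_cache <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "mol_bridge.py", package = "orcoscreen")
  if (!nzchar(path)) {
    # running from a source checkout (e.g. pkgload)
    path <- file.path("inst", "python", "mol_bridge.py")
  }
  path
}

#' Is the RDKit python bridge available?
#'
#' @return `TRUE` if a `python` interpreter with RDKit is on the PATH.
#' @export
rdkit_available <- function() {
  if (!is.null(.bridge_cache$available)) {
    return(.bridge_cache$available)
  }
  py <- Sys.which("python")
  ok <- nzchar(py) &&
    identical(
      suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                               stdout = FALSE, stderr = FALSE)), 0L)
  assign("available", ok, envir = .bridge_cache)
  ok
}

mol_bridge <- function(mode, payload) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("no 'python' interpreter on PATH; the RDKit bridge is unavailable")
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(py, c(bridge_script(), mode, fin, fout),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("RDKit bridge call failed (mode '", mode, "')")
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

#' Parse SMILES into heavy-atom molecular graphs
#'
#' Returns, per molecule, the heavy-atom table (element, aromaticity,
#' hybridisation, formal charge, degree, implicit hydrogen count, Crippen
#' atomic logP contribution and approximate per-atom van der Waals surface
#' area) and the bond list. Results are memoised for the session.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of molecular graphs (`NULL` for unparsable entries), each of
#'   class `mol_graph` with elements `atoms` (data.frame), `bonds`
#'   (data.frame), `n_heavy` and `smiles`.
#' @export
mol_graphs <- function(smiles) {
  key <- paste0("g:", smiles)
  missing <- smiles[!vapply(key, exists, logical(1), envir = .bridge_cache)]
  if (length(missing) > 0) {
    res <- mol_bridge("parse", list(smiles = as.list(unique(missing))))
    for (i in seq_along(unique(missing))) {
      smi <- unique(missing)[i]
      g <- res$graphs[[i]]
      assign(paste0("g:", smi),
             if (is.null(g)) list(NULL) else list(.as_graph(g, smi)),
             envir = .bridge_cache)
    }
  }
  lapply(key, function(k) get(k, envir = .bridge_cache)[[1]])
}

.as_graph <- function(g, smiles_in) {
  atoms <- do.call(rbind, lapply(g$atoms, function(a) {
    data.frame(element = a$element, aromatic = a$aromatic, hyb = a$hyb,
               charge = a$charge, degree = a$degree, n_h = a$n_h,
               in_ring = a$in_ring, crippen_logp = a$crippen_logp,
               vsa = a$vsa, stringsAsFactors = FALSE)
  }))
  bonds <- if (length(g$bonds) == 0) {
    data.frame(i = integer(), j = integer(), order = numeric(),
               aromatic = logical())
  } else {
    do.call(rbind, lapply(g$bonds, function(b) {
      data.frame(i = b$i, j = b$j, order = b$order, aromatic = b$aromatic)
    }))
  }
  structure(
    list(atoms = atoms, bonds = bonds, n_heavy = g$n_heavy,
         smiles = smiles_in, smiles_canonical = g$smiles_canonical),
    class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles_canonical, ": ", x$n_heavy, " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Generate a seeded conformer ensemble
#'
#' ETKDG distance-geometry embedding followed by MMFF94 relaxation;
#' conformers closer than `dedup_rms` (heavy-atom RMSD) are pruned during
#' embedding. Deterministic for a fixed seed.
#'
#' @param smiles single SMILES string.
#' @param n maximum number of conformers (default 100).
#' @param seed integer random seed (default 2024).
#' @param dedup_rms RMSD pruning threshold in Angstrom (default 0.5).
#' @return object of class `conformer_ensemble`: list with `smiles`,
#'   `conformers` (list of n_heavy x 3 coordinate matrices), `seed`.
#' @export
generate_conformers <- function(smiles, n = 100, seed = 2024,
                                dedup_rms = 0.5) {
  stopifnot(length(smiles) == 1, n >= 1)
  key <- paste("e", smiles, n, seed, dedup_rms, sep = ":")
  if (exists(key, envir = .bridge_cache)) {
    return(get(key, envir = .bridge_cache))
  }
  res <- mol_bridge("embed", list(smiles = list(smiles), n = n, seed = seed,
                                  dedup_rms = dedup_rms))
  ens <- res$ensembles[[1]]
  if (!is.null(ens$error)) {
    stop("conformer generation failed for '", smiles, "': ", ens$error)
  }
  confs <- lapply(ens$conformers, function(cc) {
    do.call(rbind, lapply(cc, function(xyz) as.numeric(unlist(xyz))))
  })
  out <- structure(list(smiles = smiles, conformers = confs, seed = seed,
                        n_requested = n, dedup_rms = dedup_rms),
                   class = "conformer_ensemble")
  assign(key, out, envir = .bridge_cache)
  out
}

#' Fully extended (all-anti) conformer
#'
#' Embeds one conformer, relaxes it with MMFF94 and then sets every acyclic
#' heavy-atom torsion to 180 degrees. Used to measure maximum feature
#' separations of flexible chains.
#'
#' @inheritParams generate_conformers
#' @return n_heavy x 3 coordinate matrix (Angstrom).
#' @export
extended_conformer <- function(smiles, seed = 2024) {
  res <- mol_bridge("extended", list(smiles = list(smiles), seed = seed))
  cf <- res$conformers[[1]]
  if (!is.null(cf$error)) {
    stop("extended conformer failed for '", smiles, "': ", cf$error)
  }
  do.call(rbind, lapply(cf$conformer, function(xyz) as.numeric(unlist(xyz))))
}
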