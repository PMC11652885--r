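# Ligand-based pharmacophore: feature annotation of 3D conformers,
# alignment-free distance-matrix matching, compound screening, and model
# elucidation from actives/inactives.
#
# Feature kinds (Unified-style annotation):
#   HydA  atom-centred hydrophobic point (every uncharged carbon)
#   Hyd   centroid of a contiguous hydrophobic atom group
#   Acc   H-bond acceptor heavy atom (O; nitrile and aromatic N)
#   Acc2  projected potential H-bond donor location, 2.8 A from an Acc atom
#         along its idealised lone-pair directions
# A Hyd model feature accepts Hyd or HydA annotation points (an atom is a
# degenerate centroid); a HydA model feature requires an atom-centred point.

.KIND_RADIUS <- c(Hyd = 1.0, HydA = 0.7, Acc = 1.0, Acc2 = 1.0, Don = 1.0)
.KIND_ACCEPTS <- list(Hyd = c("Hyd", "HydA"), HydA = "HydA", Acc = "Acc",
                      Acc2 = "Acc2", Don = "Don")
.ACC2_DIST <- 2.8

#' Construct a pharmacophore model
#'
#' @param kinds character vector of feature kinds (length m).
#' @param distances m x m symmetric matrix of inter-feature distances (A).
#' @param radii feature tolerance radii; default 0.7 A for `HydA`, 1.0 A
#'   otherwise.
#' @param note free-text provenance note.
#' @return object of class `pharm_model`.
#' @export
pharm_model <- function(kinds, distances, radii = NULL, note = "") {
  m <- length(kinds)
  stopifnot(all(kinds %in% names(.KIND_RADIUS)))
  distances <- as.matrix(distances)
  stopifnot(nrow(distances) == m, ncol(distances) == m)
  if (max(abs(distances - t(distances))) > 1e-9) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(distances) != 0) || any(distances[upper.tri(distances)] <= 0)) {
    stop("off-diagonal distances must be positive, diagonal zero")
  }
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(m)) {
    if (distances[i, j] > distances[i, k] + distances[k, j] + 1e-9) {
      stop("distance matrix violates the triangle inequality")
    }
  }
  if (is.null(radii)) radii <- unname(.KIND_RADIUS[kinds])
  structure(list(kinds = kinds, distances = distances, radii = radii,
                 note = note),
            class = "pharm_model")
}

#' @export
print.pharm_model <- function(x, ...) {
  cat("<pharm_model> ", length(x$kinds), " features: ",
      paste(x$kinds, collapse = ", "), "\n", sep = "")
  d <- round(x$distances, 2)
  dimnames(d) <- list(x$kinds, x$kinds)
  print(d)
  invisible(x)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate geometry: zero-length direction")
  v / n
}

.any_perp <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(pracma_cross(v, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# idealised lone-pair directions for an acceptor atom (unit vectors)
.lone_pair_dirs <- function(graph, coords, i) {
  at <- graph$atoms
  nb <- .neighbours(graph, i)
  dirs <- list()
  bond_vecs <- lapply(nb, function(j) .unit(coords[j, ] - coords[i, ]))
  el <- at$element[i]
  sp <- at$hyb[i]
  if (el == "N" && sp == "SP" && length(nb) == 1) {
    # nitrile: single axial lone pair
    dirs[[1]] <- -bond_vecs[[1]]
  } else if (length(nb) == 1 && (sp == "SP2" || isTRUE(at$aromatic[i]))) {
    # carbonyl-type oxygen: two in-plane lone pairs at 120 deg from the
    # bond, i.e. the reversed bond vector rotated by +-60 deg in the sp2
    # plane (defined by the carbon's other substituent)
    j <- nb[1]
    others <- setdiff(.neighbours(graph, j), i)
    plane_ref <- if (length(others) > 0) {
      .unit(coords[others[1], ] - coords[j, ])
    } else {
      .any_perp(bond_vecs[[1]])
    }
    w <- .unit(pracma_cross(bond_vecs[[1]], plane_ref))
    inplane <- .unit(pracma_cross(w, bond_vecs[[1]]))
    dirs[[1]] <- .unit(-bond_vecs[[1]] * cos(pi / 3) + inplane * sin(pi / 3))
    dirs[[2]] <- .unit(-bond_vecs[[1]] * cos(pi / 3) - inplane * sin(pi / 3))
  } else if (length(nb) == 2) {
    # ether / epoxide oxygen or aromatic nitrogen
    bisect <- -(bond_vecs[[1]] + bond_vecs[[2]])
    if (sqrt(sum(bisect^2)) < 1e-6) bisect <- .any_perp(bond_vecs[[1]])
    bisect <- .unit(bisect)
    if (el == "N") {
      dirs[[1]] <- bisect           # pyridine-like: one in-plane lone pair
    } else {
      w <- .unit(pracma_cross(bond_vecs[[1]], bond_vecs[[2]]))
      half <- (109.47 / 2) * pi / 180
      dirs[[1]] <- .unit(bisect * cos(half) + w * sin(half))
      dirs[[2]] <- .unit(bisect * cos(half) - w * sin(half))
    }
  } else if (length(nb) == 1) {
    # hydroxyl oxygen with implicit H: three tetrahedral directions at
    # 109.47 deg from the O-C bond (2 lone pairs + the donor H position,
    # all plausible donor-approach sites); azimuth anchored on the carbon's
    # first other substituent for determinism
    axis <- bond_vecs[[1]]
    j <- nb[1]
    others <- setdiff(.neighbours(graph, j), i)
    ref <- if (length(others) > 0) {
      .unit(coords[others[1], ] - coords[j, ])
    } else {
      .any_perp(axis)
    }
    w1 <- .unit(ref - sum(ref * axis) * axis)
    w2 <- pracma_cross(axis, w1)
    ang <- 109.47 * pi / 180
    for (phi in c(0, 2 * pi / 3, 4 * pi / 3)) {
      dirs[[length(dirs) + 1]] <-
        .unit(axis * cos(ang) + (w1 * cos(phi) + w2 * sin(phi)) * sin(ang))
    }
  }
  dirs
}

.is_acceptor <- function(graph, i) {
  at <- graph$atoms
  if (at$charge[i] != 0) return(FALSE)
  if (at$element[i] == "O") return(TRUE)
  if (at$element[i] == "N") {
    if (at$hyb[i] == "SP" && at$degree[i] == 1) return(TRUE)   # nitrile
    if (isTRUE(at$aromatic[i]) && at$n_h[i] == 0) return(TRUE) # pyridine
  }
  FALSE
}

#' Annotate pharmacophore feature points on a conformer
#'
#' @param graph `mol_graph` of the molecule (heavy atoms).
#' @param coords n_heavy x 3 coordinate matrix (A), rows aligned with
#'   `graph$atoms`.
#' @return data.frame of class `feature_points`: `kind`, `x`, `y`, `z`,
#'   `parent` (comma-separated atom indices), `projected`.
#' @export
annotate_features <- function(graph, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != graph$n_heavy || ncol(coords) != 3 ||
      any(!is.finite(coords))) {
    stop("coords must be a finite n_heavy x 3 matrix")
  }
  rows <- list()
  add <- function(kind, xyz, parent, projected = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, x = xyz[1], y = xyz[2], z = xyz[3],
      parent = paste(parent, collapse = ","), projected = projected,
      stringsAsFactors = FALSE)
  }
  at <- graph$atoms
  hyd <- which(at$element == "C" & at$charge == 0)
  for (i in hyd) add("HydA", coords[i, ], i)
  # contiguous hydrophobic groups -> centroids
  if (length(hyd) > 0) {
    comp <- stats::setNames(seq_along(hyd), as.character(hyd))
    hb <- graph$bonds[graph$bonds$i %in% hyd & graph$bonds$j %in% hyd, ,
                      drop = FALSE]
    repeat {
      changed <- FALSE
      for (b in seq_len(nrow(hb))) {
        ci <- comp[as.character(hb$i[b])]
        cj <- comp[as.character(hb$j[b])]
        if (ci != cj) {
          comp[comp == max(ci, cj)] <- min(ci, cj)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(comp)) {
      members <- as.integer(names(comp)[comp == g])
      if (length(members) >= 2) {
        add("Hyd", colMeans(coords[members, , drop = FALSE]), members)
      }
    }
  }
  for (i in seq_len(nrow(at))) {
    if (!.is_acceptor(graph, i)) next
    add("Acc", coords[i, ], i)
    for (d in .lone_pair_dirs(graph, coords, i)) {
      add("Acc2", coords[i, ] + .ACC2_DIST * d, i, projected = TRUE)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(kind = character(), x = numeric(), y = numeric(),
               z = numeric(), parent = character(), projected = logical(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("feature_points", "data.frame")
  out
}

#' Match annotated feature points against a pharmacophore model
#'
#' Searches assignments of distinct, kind-compatible points to the model
#' features such that every inter-point distance deviates from the model
#' distance by at most the sum of the two feature radii; returns the
#' assignment minimising the maximum deviation.
#'
#' @param points `feature_points` data.frame (or anything with columns
#'   `kind`, `x`, `y`, `z`).
#' @param model `pharm_model`.
#' @param first_match if `TRUE`, stop at the first feasible assignment
#'   instead of optimising the deviation (faster screening).
#' @return list: `matched`, `assignment` (point row per feature, or `NULL`),
#'   `max_distance_error`.
#' @export
match_points <- function(points, model, first_match = FALSE) {
  m <- length(model$kinds)
  P <- as.matrix(points[, c("x", "y", "z")])
  cand <- lapply(model$kinds, function(k) {
    which(points$kind %in% .KIND_ACCEPTS[[k]])
  })
  if (any(vapply(cand, length, integer(1)) == 0)) {
    return(list(matched = FALSE, assignment = NULL,
                max_distance_error = NA_real_))
  }
  pd <- as.matrix(stats::dist(P))
  tol <- outer(model$radii, model$radii, "+")
  ord <- order(vapply(cand, length, integer(1)))
  best <- list(dev = Inf, assign = NULL)
  assign_vec <- integer(m)
  rec <- function(pos, cur_dev) {
    if (!is.infinite(best$dev) && first_match) return()
    if (pos > m) {
      if (cur_dev < best$dev) best <<- list(dev = cur_dev, assign = assign_vec)
      return()
    }
    f <- ord[pos]
    for (p in cand[[f]]) {
      if (pos > 1 && p %in% assign_vec[ord[seq_len(pos - 1)]]) next
      dev <- cur_dev
      ok <- TRUE
      if (pos > 1) {
        for (q in seq_len(pos - 1)) {
          g <- ord[q]
          dd <- abs(pd[p, assign_vec[g]] - model$distances[f, g])
          if (dd > tol[f, g]) { ok <- FALSE; break }
          if (dd > dev) dev <- dd
        }
      }
      if (!ok || dev >= best$dev) next
      assign_vec[f] <<- p
      rec(pos + 1, dev)
      assign_vec[f] <<- 0L
    }
  }
  rec(1, 0)
  if (is.null(best$assign)) {
    list(matched = FALSE, assignment = NULL, max_distance_error = NA_real_)
  } else {
    list(matched = TRUE, assignment = best$assign,
         max_distance_error = best$dev)
  }
}

#' Annotate every conformer of an ensemble
#'
#' @param smiles SMILES string.
#' @param n,seed,dedup_rms conformer parameters, see [generate_conformers()].
#' @return list of `feature_points`, one per conformer; attribute `graph`.
#' @export
annotated_ensemble <- function(smiles, n = 100, seed = 2024,
                               dedup_rms = 0.5) {
  g <- mol_graphs(smiles)[[1]]
  if (is.null(g)) stop("unparsable SMILES: '", smiles, "'")
  ens <- generate_conformers(smiles, n = n, seed = seed,
                             dedup_rms = dedup_rms)
  out <- lapply(ens$conformers, function(cc) annotate_features(g, cc))
  attr(out, "graph") <- g
  attr(out, "smiles") <- smiles
  out
}

#' Screen one compound against a pharmacophore model
#'
#' A compound matches when any conformer of its ensemble matches.
#'
#' @param smiles SMILES string (or a fixture row with `$smiles`).
#' @param model `pharm_model`.
#' @param n,seed,dedup_rms conformer ensemble parameters.
#' @param points optional pre-annotated ensemble (list of `feature_points`)
#'   overriding conformer generation.
#' @return list of class `match_result`: `matched`, `conformer_index`,
#'   `max_distance_error`, `n_conformers`.
#' @export
screen_compound <- function(smiles, model, n = 100, seed = 2024,
                            dedup_rms = 0.5, points = NULL) {
  if (is.list(smiles) && !is.null(smiles$smiles)) smiles <- smiles$smiles
  ens <- if (is.null(points)) {
    annotated_ensemble(smiles, n = n, seed = seed, dedup_rms = dedup_rms)
  } else {
    points
  }
  best <- NULL
  for (ci in seq_along(ens)) {
    res <- match_points(ens[[ci]], model, first_match = FALSE)
    if (res$matched &&
        (is.null(best) || res$max_distance_error < best$max_distance_error)) {
      best <- list(matched = TRUE, conformer_index = ci,
                   max_distance_error = res$max_distance_error,
                   assignment = res$assignment)
    }
  }
  out <- if (is.null(best)) {
    list(matched = FALSE, conformer_index = NA_integer_,
         max_distance_error = NA_real_, assignment = NULL)
  } else {
    best
  }
  out$n_conformers <- length(ens)
  structure(out, class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<match_result> matched (conformer %d, max error %.2f A)\n",
                x$conformer_index, x$max_distance_error))
  } else {
    cat("<match_result> not matched\n")
  }
  invisible(x)
}

# canonical signature of a typed distance configuration on the 0.9 A grid
.config_signature <- function(kinds, dmat, grid = 0.9) {
  m <- length(kinds)
  snapped <- round(dmat / grid) * grid
  perms <- .permutations_within_kind(kinds)
  sigs <- vapply(perms, function(p) {
    paste(c(kinds[p][order(seq_len(m))],
            sprintf("%.2f", snapped[p, p][upper.tri(dmat)])),
          collapse = "|")
  }, character(1))
  min(sigs)
}

.permutations_within_kind <- function(kinds) {
  # permutations of feature slots that keep kinds fixed (e.g. swap Hyd1/Hyd2)
  groups <- split(seq_along(kinds), kinds)
  perm_list <- list(seq_along(kinds))
  for (g in groups) {
    if (length(g) < 2) next
    gperms <- .all_perms(g)
    new_list <- list()
    for (base in perm_list) {
      for (gp in gperms) {
        p <- base
        p[g] <- gp
        new_list[[length(new_list) + 1]] <- p
      }
    }
    perm_list <- new_list
  }
  perm_list
}

.all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .all_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# enumerate typed point tuples of one conformer and return snapped signatures
.conformer_signatures <- function(points, kinds, grid = 0.9,
                                  clamp = NULL) {
  cand <- lapply(kinds, function(k) which(points$kind %in% .KIND_ACCEPTS[[k]]))
  if (any(vapply(cand, length, integer(1)) == 0)) return(character(0))
  P <- as.matrix(points[, c("x", "y", "z")])
  pd <- as.matrix(stats::dist(P))
  tuples <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  keep <- apply(tuples, 1, function(tt) !anyDuplicated(tt))
  tuples <- tuples[keep, , drop = FALSE]
  if (nrow(tuples) == 0) return(character(0))
  sigs <- character(0)
  for (r in seq_len(nrow(tuples))) {
    idx <- as.integer(tuples[r, ])
    dmat <- pd[idx, idx]
    if (!is.null(clamp)) {
      # clamp: named list, e.g. list(pair=c(1,2), dist=7.2, tol=0.45)
      if (abs(dmat[clamp$pair[1], clamp$pair[2]] - clamp$dist) > clamp$tol) {
        next
      }
    }
    if (min(dmat[upper.tri(dmat)]) < grid / 2) next  # degenerate overlap
    sigs <- c(sigs, .config_signature(kinds, dmat, grid))
  }
  unique(sigs)
}

.signature_to_model <- function(sig, note = "") {
  parts <- strsplit(sig, "|", fixed = TRUE)[[1]]
  m_guess <- (-1 + sqrt(1 + 8 * length(parts))) / 2  # m + m(m-1)/2 entries
  m <- floor(m_guess)
  kinds <- parts[seq_len(m)]
  dvals <- as.numeric(parts[-seq_len(m)])
  dmat <- matrix(0, m, m)
  dmat[upper.tri(dmat)] <- dvals
  dmat <- dmat + t(dmat)
  pharm_model(kinds, dmat, note = note)
}

#' Elucidate pharmacophore models from actives and inactives
#'
#' Enumerates typed feature-point configurations (inter-feature distances
#' snapped to a 0.9 A grid) present in every active's conformer ensemble,
#' verifies each surviving candidate with the matcher (active coverage 1),
#' and ranks candidates by ascending inactive (false-positive) match count,
#' then by feature count descending, then by signature.
#'
#' @param actives,inactives character vectors of SMILES, or lists of
#'   pre-annotated ensembles (see [annotated_ensemble()]).
#' @param kinds feature kind template (default two `Hyd`, one `HydA`, one
#'   `Acc2`).
#' @param n,seed,dedup_rms conformer parameters.
#' @param grid discretisation step of candidate distances (query spacing).
#' @param clamp optional distance constraint, e.g.
#'   `list(pair = c(1, 2), dist = 7.2, tol = 0.45)`.
#' @param max_models maximum number of ranked models returned.
#' @return list of `pharm_model`s, each with attributes `fp_count` and
#'   `signature`; empty (with a message) when no candidate covers all
#'   actives.
#' @export
elucidate <- function(actives, inactives = list(),
                      kinds = c("Hyd", "Hyd", "HydA", "Acc2"),
                      n = 50, seed = 2024, dedup_rms = 0.5, grid = 0.9,
                      clamp = NULL, max_models = 20) {
  as_ens <- function(x) {
    if (is.character(x)) {
      lapply(x, annotated_ensemble, n = n, seed = seed,
             dedup_rms = dedup_rms)
    } else {
      x
    }
  }
  act <- as_ens(actives)
  inact <- as_ens(inactives)
  if (length(act) < 1) stop("need at least one active")
  # candidate configurations are enumerated from the active with the
  # fewest distinct grid signatures (grid snapping is only used to
  # discretise/deduplicate candidates; commonality across actives is then
  # enforced with the matcher itself, whose tolerance is the sum of the
  # feature radii)
  sig_sets <- lapply(act, function(ens) {
    unique(unlist(lapply(ens, .conformer_signatures, kinds = kinds,
                         grid = grid, clamp = clamp)))
  })
  common <- sig_sets[[which.min(lengths(sig_sets))]]
  if (length(common) == 0) {
    message("elucidate: no candidate configuration in the reference active")
    return(list())
  }
  # snapping can nudge a realisable configuration off the triangle
  # inequality; such candidates are geometrically inconsistent and dropped
  models <- lapply(common, function(s) {
    tryCatch(.signature_to_model(s, note = "elucidated on the 0.9 A grid"),
             error = function(e) NULL)
  })
  common <- common[!vapply(models, is.null, logical(1))]
  models <- models[!vapply(models, is.null, logical(1))]
  if (length(models) == 0) {
    message("elucidate: no geometrically consistent candidate")
    return(list())
  }
  # verify active coverage with the matcher, count inactive matches
  keep <- logical(length(models))
  fp <- integer(length(models))
  for (i in seq_along(models)) {
    ok <- all(vapply(act, function(ens) {
      screen_compound(NULL, models[[i]], points = ens)$matched
    }, logical(1)))
    keep[i] <- ok
    if (ok) {
      fp[i] <- sum(vapply(inact, function(ens) {
        screen_compound(NULL, models[[i]], points = ens)$matched
      }, logical(1)))
    }
  }
  models <- models[keep]
  fp <- fp[keep]
  sigs <- common[keep]
  if (length(models) == 0) {
    message("elucidate: no candidate matched all actives under the matcher")
    return(list())
  }
  nf <- vapply(models, function(m) length(m$kinds), integer(1))
  # final tie-break: prefer well-separated features (the elucidated query
  # should be four distinct spheres, not nested ones), then signature
  minsep <- vapply(models, function(m) min(m$distances[upper.tri(m$distances)]),
                   numeric(1))
  ord <- order(fp, -nf, -minsep, sigs)
  models <- models[ord][seq_len(min(max_models, length(models)))]
  for (i in seq_along(models)) {
    attr(models[[i]], "fp_count") <- fp[ord][i]
    attr(models[[i]], "signature") <- sigs[ord][i]
  }
  models
}

#' Serialise / restore a pharmacophore model as JSON
#'
#' @param model `pharm_model`.
#' @param path JSON file.
#' @export
pharm_to_json <- function(model, path) {
  jsonlite::write_json(list(kinds = model$kinds,
                            distances = model$distances,
                            radii = model$radii, note = model$note),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname pharm_to_json
#' @export
pharm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pharm_model(as.character(obj$kinds), as.matrix(obj$distances),
              radii = as.numeric(obj$radii), note = obj$note)
}

#' The shipped ORco orthosteric-antagonist pharmacophore model
#'
#' Four features (two centroid hydrophobics 7.2 A apart, one atom-centred
#' hydrophobic, one projected H-bond donor location), calibrated by running
#' [elucidate()] on the four known orthosteric antagonists against the three
#' allosteric antagonists with the Hyd1-Hyd2 distance clamped at 7.2 A.
#'
#' @return `pharm_model`.
#' @export
orco_model <- function() {
  path <- system.file("extdata", "orco_pharmacophore.json",
                      package = "orcoscreen")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "orco_pharmacophore.json")
  }
  pharm_from_json(path)
}

#' Maximum hydrophobic feature separation of a conformer
#'
#' Annotates a conformer and reports the largest pairwise distance between
#' hydrophobic (Hyd/HydA) points — e.g. to check a chain against the
#' model's 7.2 A Hyd1-Hyd2 requirement.
#'
#' @param graph `mol_graph`; @param coords conformer coordinates.
#' @return distance in Angstrom.
#' @export
max_hyd_separation <- function(graph, coords) {
  pts <- annotate_features(graph, coords)
  hyd <- pts[pts$kind %in% c("Hyd", "HydA"), c("x", "y", "z")]
  if (nrow(hyd) < 2) return(NA_real_)
  max(stats::dist(as.matrix(hyd)))
}
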