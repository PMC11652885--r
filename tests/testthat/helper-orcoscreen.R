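# Shared test helpers: synthetic geometry builders and independent oracles.

# embed a distance matrix as 3D points (exact for realisable matrices)
points_from_dist <- function(D, kinds) {
  P <- stats::cmdscale(stats::as.dist(D), k = min(3, nrow(D) - 1))
  if (ncol(P) < 3) P <- cbind(P, matrix(0, nrow(P), 3 - ncol(P)))
  out <- data.frame(kind = kinds, x = P[, 1], y = P[, 2], z = P[, 3],
                    parent = NA_character_, projected = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_points", "data.frame")
  out
}

# brute-force matcher oracle: enumerate every assignment of distinct,
# kind-compatible points; return feasibility and minimal max deviation
match_oracle <- function(points, model) {
  kind_accepts <- list(Hyd = c("Hyd", "HydA"), HydA = "HydA", Acc = "Acc",
                       Acc2 = "Acc2", Don = "Don")
  m <- length(model$kinds)
  cand <- lapply(model$kinds, function(k) which(points$kind %in%
                                                  kind_accepts[[k]]))
  P <- as.matrix(points[, c("x", "y", "z")])
  pd <- as.matrix(stats::dist(P))
  tol <- outer(model$radii, model$radii, "+")
  best <- Inf
  assign_rec <- function(chosen) {
    pos <- length(chosen) + 1
    if (pos > m) {
      dev <- 0
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        dd <- abs(pd[chosen[a], chosen[b]] - model$distances[a, b])
        if (dd > tol[a, b]) return(invisible())
        dev <- max(dev, dd)
      }
      best <<- min(best, dev)
      return(invisible())
    }
    for (p in setdiff(cand[[pos]], chosen)) assign_rec(c(chosen, p))
  }
  assign_rec(integer(0))
  list(matched = is.finite(best),
       max_distance_error = if (is.finite(best)) best else NA_real_)
}

# random realisable model + point cloud generator for matcher property tests
random_match_case <- function(n_points = 6, seed = 1) {
  set.seed(seed)
  kinds_pool <- c("Hyd", "HydA", "HydA", "Acc2", "Acc", "Hyd")
  pts <- data.frame(
    kind = sample(kinds_pool, n_points, replace = TRUE),
    x = stats::runif(n_points, 0, 8), y = stats::runif(n_points, 0, 8),
    z = stats::runif(n_points, 0, 8), parent = NA_character_,
    projected = FALSE, stringsAsFactors = FALSE)
  class(pts) <- c("feature_points", "data.frame")
  m <- sample(3:4, 1)
  mkinds <- sample(c("Hyd", "HydA", "Acc2"), m, replace = TRUE)
  anchor <- matrix(stats::runif(m * 3, 0, 8), m, 3)
  D <- as.matrix(stats::dist(anchor))
  model <- pharm_model(mkinds, D)
  list(points = pts, model = model)
}

# python/RDKit descriptor oracle (tiny fixture use only)
rdkit_descriptor <- function(smiles, what = c("Kappa2", "SlogP_VSA2")) {
  what <- match.arg(what)
  code <- sprintf(
    "from rdkit import Chem; from rdkit.Chem import Descriptors; import sys; print(repr(Descriptors.%s(Chem.MolFromSmiles(sys.argv[1]))))",
    what)
  out <- system2("python", c("-c", shQuote(code), shQuote(smiles)),
                 stdout = TRUE)
  as.numeric(out[length(out)])
}

table5_xy <- function() {
  t5 <- load_fixture("T5")
  list(x = as.matrix(t5[, c("kier_a2", "slogp_vsa1")]),
       y = t5$active_orthosteric, ids = t5$compound_id, fixture = t5)
}

# coarse but adequate hyperparameter grid to keep test runtimes down
coarse_grid <- function() list(gamma = 10^seq(-2, 2, by = 1),
                               C = 10^seq(-1, 3, by = 1))
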