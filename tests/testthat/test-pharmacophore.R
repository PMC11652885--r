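test_that("hydrocarbons annotate as hydrophobic-only", {
  g <- mol_graphs("CCCCCC")[[1]]
  ens <- generate_conformers("CCCCCC", n = 3, seed = 1)
  pts <- annotate_features(g, ens$conformers[[1]])
  expect_gte(sum(pts$kind == "Hyd"), 1)
  expect_equal(sum(pts$kind == "HydA"), 6)
  expect_equal(sum(pts$kind %in% c("Acc", "Acc2")), 0)
})

test_that("ester conformers carry hydrophobics and projected acceptors", {
  g <- mol_graphs("CCOC(=O)/C=C/c1ccccc1")[[1]]
  ens <- generate_conformers("CCOC(=O)/C=C/c1ccccc1", n = 3, seed = 1)
  pts <- annotate_features(g, ens$conformers[[1]])
  expect_gte(sum(pts$kind %in% c("Hyd", "HydA")), 2)
  expect_equal(sum(pts$kind == "Acc"), 2)      # both ester oxygens
  expect_gte(sum(pts$kind == "Acc2"), 2)
  expect_true(all(pts$projected[pts$kind == "Acc2"]))
})

test_that("lone-pair projections obey idealised geometry", {
  # methanol-like single acceptor: 3 tetrahedral projections at 2.8 A
  g <- mol_graphs("CO")[[1]]
  ens <- generate_conformers("CO", n = 1, seed = 1)
  xyz <- ens$conformers[[1]]
  pts <- annotate_features(g, xyz)
  acc2 <- pts[pts$kind == "Acc2", c("x", "y", "z")]
  expect_equal(nrow(acc2), 3)
  o_idx <- which(g$atoms$element == "O")
  c_idx <- which(g$atoms$element == "C")
  for (r in seq_len(3)) {
    v <- as.numeric(acc2[r, ]) - xyz[o_idx, ]
    expect_equal(sqrt(sum(v^2)), 2.8, tolerance = 1e-6)
    bond <- xyz[c_idx, ] - xyz[o_idx, ]
    ang <- acos(sum(v * bond) / sqrt(sum(v^2) * sum(bond^2))) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.1)
  }
  # acetone: 2 in-plane carbonyl lone pairs at 120 deg from the C=O bond
  g2 <- mol_graphs("CC(C)=O")[[1]]
  xyz2 <- generate_conformers("CC(C)=O", n = 1, seed = 1)$conformers[[1]]
  pts2 <- annotate_features(g2, xyz2)
  acc2b <- pts2[pts2$kind == "Acc2", c("x", "y", "z")]
  expect_equal(nrow(acc2b), 2)
  o2 <- which(g2$atoms$element == "O")
  carbonyl <- which(g2$atoms$element == "C" & g2$atoms$degree == 3)
  bond <- xyz2[carbonyl, ] - xyz2[o2, ]
  for (r in seq_len(2)) {
    v <- as.numeric(acc2b[r, ]) - xyz2[o2, ]
    ang <- acos(sum(v * bond) / sqrt(sum(v^2) * sum(bond^2))) * 180 / pi
    expect_equal(ang, 120, tolerance = 0.1)
  }
})

test_that("a point set at exact model distances matches with zero error", {
  D <- matrix(0, 4, 4)
  D[1, 2] <- 7.2; D[1, 3] <- 3; D[2, 3] <- 4.5
  D[1, 4] <- 5; D[2, 4] <- 4; D[3, 4] <- 3.5
  D <- D + t(D)
  mdl <- pharm_model(c("Hyd", "Hyd", "HydA", "Acc2"), D)
  pts <- points_from_dist(D, c("HydA", "HydA", "HydA", "Acc2"))
  res <- match_points(pts, mdl)
  expect_true(res$matched)
  expect_lt(res$max_distance_error, 1e-6)
})

test_that("matcher agrees with the exhaustive assignment oracle", {
  for (seed in 1:40) {
    case <- random_match_case(n_points = 6, seed = seed)
    got <- match_points(case$points, case$model)
    want <- match_oracle(case$points, case$model)
    expect_equal(got$matched, want$matched, label = paste("seed", seed))
    if (want$matched) {
      expect_equal(got$max_distance_error, want$max_distance_error,
                   tolerance = 1e-9, label = paste("seed", seed))
    }
  }
})

test_that("kind compatibility: HydA features reject centroid points", {
  D <- matrix(c(0, 3, 3, 0), 2, 2)
  mdl_hydA <- pharm_model(c("HydA", "HydA"), D)
  pts <- points_from_dist(D, c("Hyd", "Hyd"))
  expect_false(match_points(pts, mdl_hydA)$matched)
  mdl_hyd <- pharm_model(c("Hyd", "Hyd"), D)
  expect_true(match_points(pts, mdl_hyd)$matched)
})

test_that("matching is conformer- and tolerance-monotone", {
  mdl <- orco_model()
  ens <- annotated_ensemble("CCOC(=O)/C=C/c1ccccc1", n = 20, seed = 2024)
  full <- screen_compound(NULL, mdl, points = ens)
  expect_true(full$matched)
  # adding conformers can only create matches, never destroy them
  sub <- screen_compound(NULL, mdl, points = ens[full$conformer_index])
  expect_true(sub$matched)
  # enlarging all radii never loses a match
  for (seed in 1:10) {
    case <- random_match_case(n_points = 5, seed = seed)
    before <- match_points(case$points, case$model)
    bigger <- case$model
    bigger$radii <- bigger$radii + 0.5
    after <- match_points(case$points, bigger)
    if (before$matched) expect_true(after$matched)
  }
})

test_that("conformer generation is seeded, deduplicated and robust", {
  rigid <- generate_conformers("c1ccccc1", n = 50, seed = 3)
  expect_equal(length(rigid$conformers), 1)   # benzene: one shape
  a <- generate_conformers("CCCCCC(=O)O", n = 25, seed = 11)
  b <- generate_conformers("CCCCCC(=O)O", n = 25, seed = 11)
  expect_identical(a$conformers, b$conformers)
  t3 <- load_fixture("T3")
  macro <- t3$smiles[t3$compound_id == "84"]
  expect_gte(length(generate_conformers(macro, n = 10, seed = 1)$conformers),
             1)
})

test_that("the shipped model has the published feature scheme", {
  mdl <- orco_model()
  expect_equal(sort(mdl$kinds), c("Acc2", "Hyd", "Hyd", "HydA"))
  hyd <- which(mdl$kinds == "Hyd")
  expect_equal(mdl$distances[hyd[1], hyd[2]], 7.2)
  expect_equal(mdl$radii[mdl$kinds == "HydA"], 0.7)
  expect_true(all(mdl$radii[mdl$kinds != "HydA"] == 1))
})

test_that("elucidation recovers a planted configuration", {
  D <- matrix(0, 4, 4)
  D[1, 2] <- 7.2; D[1, 3] <- 3.6; D[2, 3] <- 4.4
  D[1, 4] <- 5.3; D[2, 4] <- 4.1; D[3, 4] <- 3.4
  D <- D + t(D)
  planted_kinds <- c("HydA", "HydA", "HydA", "Acc2")
  set.seed(42)
  make_active <- function() {
    pts <- points_from_dist(D, planted_kinds)
    # add decoy points far away so the planted config stays unique
    decoys <- data.frame(kind = c("HydA", "Acc2"),
                         x = stats::runif(2, 20, 30),
                         y = stats::runif(2, 20, 30),
                         z = stats::runif(2, 20, 30),
                         parent = NA_character_, projected = FALSE)
    out <- rbind(pts, decoys)
    class(out) <- c("feature_points", "data.frame")
    list(out)
  }
  actives <- list(make_active(), make_active(), make_active())
  models <- elucidate(actives, list(),
                      kinds = c("Hyd", "Hyd", "HydA", "Acc2"))
  expect_gt(length(models), 0)
  # the planted configuration is recovered within the grid spacing
  want <- sort(D[upper.tri(D)])
  recovered <- vapply(models, function(m) {
    got <- sort(m$distances[upper.tri(m$distances)])
    all(abs(got - want) <= 0.45 + 1e-9)
  }, logical(1))
  expect_true(any(recovered))
})

test_that("model serialisation round-trips and validates", {
  mdl <- orco_model()
  f <- withr::local_tempfile(fileext = ".json")
  pharm_to_json(mdl, f)
  back <- pharm_from_json(f)
  expect_equal(back$distances, mdl$distances)
  expect_equal(back$kinds, mdl$kinds)
  expect_equal(back$radii, mdl$radii)

  expect_error(pharm_model("Hyd", matrix(0, 1, 1)), NA)
  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(pharm_model(c("Hyd", "Nope"), bad))
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pharm_model(c("Hyd", "Hyd"), asym), "symmetric")
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 10; tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 1
  expect_error(pharm_model(c("Hyd", "Hyd", "Hyd"), tri), "triangle")
})
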