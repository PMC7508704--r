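test_that("superposition recovers rigid transforms with a proper rotation", {
  set.seed(23)
  a <- matrix(rnorm(30), 10, 3)
  tr <- superpose(a, a)
  expect_lt(tr$rmsd, 1e-10)
  expect_equal(det(tr$R), 1, tolerance = 1e-9)

  Rm <- rnasse:::rot_axis(c(1, -1, 2), 0.9)
  b <- sweep(a %*% Rm, 2, c(3, -5, 1), "+")
  tr2 <- superpose(a, b)
  expect_lt(tr2$rmsd, 1e-9)
  expect_equal(rnasse::transform_coords(a, tr2), b, tolerance = 1e-8)

  expect_error(superpose(a[1:2, ], a[1:2, ]), "3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition RMSD matches a direct numerical minimization", {
  set.seed(29)
  for (rep in 1:5) {
    a <- matrix(rnorm(18), 6, 3)
    b <- a + matrix(rnorm(18, sd = 0.3), 6, 3)
    ours <- superpose(a, b)$rmsd
    obj <- function(par) {
      Rm <- rnasse:::rot_axis(c(sin(par[1]) * cos(par[2]),
                                sin(par[1]) * sin(par[2]),
                                cos(par[1])), par[3])
      fit <- sweep(a %*% Rm, 2, par[4:6], "+")
      sqrt(mean(rowSums((fit - b)^2)))
    }
    best <- Inf
    for (s in 1:40) {
      par0 <- c(runif(1, 0, pi), runif(1, -pi, pi), runif(1, -pi, pi),
                rnorm(3))
      o <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 200))
      best <- min(best, o$value)
    }
    expect_lt(abs(ours - best), 1e-3)
    expect_lte(ours, best + 1e-6)
  }
})

test_that("self-inclusion assembly reconstructs the fixture", {
  fx <- fixture_chain("..((((....))))..", source_id = "TOYA")
  lib <- build_library(list(fx$chain), "lib2")
  res <- assemble(fx$sequence, fx$db, lib, seed = 1)
  expect_lte(rmsd_to_reference(res, fx$raw), 0.1)
  # provenance covers every SSE
  expect_length(res$provenance, length(res$records))
  expect_true(all(vapply(res$provenance, function(p) p$source_id, "") ==
                  "TOYA"))
  # every residue has coordinates for the full heavy-atom set
  for (r in seq_along(res$seq)) {
    expect_setequal(res$atoms$atom[res$atoms$res == r],
                    ideal_nucleotide(res$seq[r])$atom)
  }
})

test_that("assembly fails with a named SSE when no template matches", {
  fx <- fixture_chain("((((....))))", source_id = "TOYA")
  lib <- build_library(list(fx$chain), "lib2")
  expect_error(assemble("GGGGAAAAACCCC", "((((.....))))", lib, seed = 1),
               "\\(\\(\\.\\.\\.\\.\\.\\)\\)")
})

test_that("assembly is deterministic and imposes the target sequence", {
  fx <- fixture_chain("..((((....))))..", source_id = "TOYA")
  lib <- build_library(list(fx$chain), "lib2")
  target <- "AAGGGGAAAACCCCAA"
  r1 <- assemble(target, fx$db, lib, seed = 7)
  r2 <- assemble(target, fx$db, lib, seed = 7)
  expect_identical(r1$atoms, r2$atoms)
  expect_equal(r1$seq, strsplit(target, "")[[1]])
  for (r in seq_along(r1$seq)) {
    expect_setequal(r1$atoms$atom[r1$atoms$res == r],
                    ideal_nucleotide(r1$seq[r])$atom)
  }
})

test_that("clash-free input passes through minimization unchanged", {
  fx <- fixture_chain("((((....))))", sq = "GGGGAAAACCCC",
                      source_id = "TOYC")
  lib <- build_library(list(fx$chain), "lib2")
  res <- assemble(fx$sequence, fx$db, lib, seed = 1)
  expect_equal(rnasse:::count_clashes(res), 0)
  out <- minimize_clashes(res)
  expect_lt(max(abs(rnasse:::result_xyz(out) - rnasse:::result_xyz(res))),
            0.05)
  expect_lte(out$energy, res$energy)
})

test_that("two rigid fragments in contact are pushed to the contact distance", {
  fx <- fixture_chain("((((....))))..((((....))))", source_id = "TOYD")
  lib <- build_library(list(fx$chain), "lib2")
  res <- assemble(fx$sequence, fx$db, lib, seed = 1)
  # engineer a 1 A approach between the two arms
  X <- rnasse:::result_xyz(res)
  arm2 <- res$atoms$res >= 15
  cm1 <- colMeans(X[res$atoms$res <= 12, ])
  cm2 <- colMeans(X[arm2, ])
  shift <- (cm1 - cm2) * (1 - 1 / sqrt(sum((cm1 - cm2)^2)))
  X[arm2, ] <- sweep(X[arm2, , drop = FALSE], 2, shift, "+")
  res2 <- rnasse:::set_result_xyz(res, X)
  res2$energy <- assembly_energy(res2)
  expect_gt(res2$energy, 0)
  out <- minimize_clashes(res2)
  expect_lte(out$energy, res2$energy)
  p <- energy_params()
  det <- rnasse:::cross_clash_energy(rnasse:::result_xyz(out), out$topology,
                                     p, 1:12, detail = TRUE)
  if (!is.null(det$d)) expect_gte(min(det$d), p$contact - 0.1)
})

test_that("SAMC plumbing: zero scorer accepts everything; degenerate schedule is static", {
  fx <- fixture_chain("..((((....))))..", source_id = "TOYE")
  lib <- build_library(list(fx$chain), "lib2")
  res <- assemble(fx$sequence, fx$db, lib, seed = 1)

  ens <- samc_optimize(res, n_steps = 200, sample_every = 10, seed = 4,
                       scorer = function(xyz, result) 0)
  expect_equal(attr(ens, "acceptance_rate"), 1)

  sched <- samc_schedule(T_start = 1, T_end = 1, max_trans = 0,
                         max_rot_deg = 0)
  ens2 <- samc_optimize(res, n_steps = 100, schedule = sched,
                        sample_every = 10, seed = 4)
  for (s in ens2) {
    expect_equal(rnasse:::result_xyz(s), rnasse:::result_xyz(res),
                 tolerance = 1e-12)
  }

  e1 <- samc_optimize(res, n_steps = 300, sample_every = 20, seed = 9)
  e2 <- samc_optimize(res, n_steps = 300, sample_every = 20, seed = 9)
  expect_identical(lapply(e1, rnasse:::result_xyz),
                   lapply(e2, rnasse:::result_xyz))
})

test_that("a single rigid SSE yields no moveable elements and a warning", {
  fx <- build_toy_rna("GGGGCCCC", "(((())))", source_id = "TOYF")
  ch <- fx$chain
  ch$ss <- fx$ss
  res <- result_from_model(ch, fx$ss, "lib2")
  expect_warning(ens <- samc_optimize(res, n_steps = 10, seed = 1),
                 "moveable")
  expect_length(ens, 1)
})

test_that("k-medoid clustering recovers planted groups and matches brute force", {
  fx <- fixture_chain("..((((....))))..", source_id = "TOYG")
  lib <- build_library(list(fx$chain), "lib2")
  base <- assemble(fx$sequence, fx$db, lib, seed = 1)
  # plant 3 well-separated conformations, 4 copies each
  make_variant <- function(shift) {
    X <- rnasse:::result_xyz(base)
    sel <- base$atoms$res <= 2
    X[sel, ] <- sweep(X[sel, , drop = FALSE], 2, shift, "+")
    r <- rnasse:::set_result_xyz(base, X)
    r$energy <- assembly_energy(r)
    r
  }
  groups <- list(make_variant(c(0, 0, 0)), make_variant(c(12, 0, 0)),
                 make_variant(c(0, 14, 5)))
  ens <- rep(groups, each = 4)
  top <- cluster_and_rank(ens, 3)
  med <- attr(top, "medoids")
  expect_equal(sort((med - 1) %/% 4), 0:2)  # one medoid per planted group

  # brute-force partition optimum on small ensembles
  small <- ens[c(1, 2, 5, 6, 9, 10)]
  xyzs <- lapply(small, rnasse:::result_xyz)
  D <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    D[i, j] <- D[j, i] <- superpose(xyzs[[j]], xyzs[[i]])$rmsd
  ours <- rnasse:::kmedoids_rmsd(D, 3)
  cost <- sum(apply(D[, ours, drop = FALSE], 1, min))
  expect_equal(cost, brute_force_medoid_cost(D, 3), tolerance = 1e-9)

  # N = 1: the medoid minimizes summed RMSD to all others
  one <- cluster_and_rank(ens[1:5], 1)
  m1 <- attr(one, "medoids")
  D5 <- matrix(0, 5, 5)
  x5 <- lapply(ens[1:5], rnasse:::result_xyz)
  for (i in 1:4) for (j in (i + 1):5)
    D5[i, j] <- D5[j, i] <- superpose(x5[[j]], x5[[i]])$rmsd
  expect_equal(m1, which.min(rowSums(D5)))

  # N = ensemble size: every member its own cluster
  distinct <- groups
  allown <- cluster_and_rank(distinct, 3)
  expect_setequal(attr(allown, "medoids"), 1:3)

  expect_warning(cluster_and_rank(groups, 5), "reducing")
})

test_that("RMSD to reference handles self, rigid copies and mismatches", {
  fx <- fixture_chain("((((....))))", source_id = "TOYH")
  lib <- build_library(list(fx$chain), "lib2")
  res <- assemble(fx$sequence, fx$db, lib, seed = 1)
  expect_equal(rmsd_to_reference(res, res), 0, tolerance = 1e-9)

  rot <- res
  Rm <- rnasse:::rot_axis(c(0, 1, 1), 2.2)
  X <- rnasse:::result_xyz(res) %*% Rm
  rot <- rnasse:::set_result_xyz(rot, sweep(X, 2, c(4, 4, 4), "+"))
  expect_equal(rmsd_to_reference(rot, res), 0, tolerance = 1e-8)

  short <- fixture_chain("(((....)))", sq = "GGGAAAACCC", source_id = "TOYI")
  expect_error(rmsd_to_reference(res, short$raw), "residue count")
})
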