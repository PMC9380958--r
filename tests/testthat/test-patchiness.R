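test_that("Voronoi volumes tile the domain and match symmetric configurations", {
  dom <- flow_domain()
  V <- 0.6 * 0.6 * 0.3

  # a single generator owns the whole box
  expect_equal(voronoi_volumes(matrix(c(0.3, 0.3, 0.15), 1), dom)$volume, V)

  # 2x2x2 lattice at cell centres: all volumes V/8 exactly
  g <- as.matrix(expand.grid(x = c(0.15, 0.45), y = c(0.15, 0.45),
                             z = c(0.075, 0.225)))
  expect_equal(voronoi_volumes(g, dom)$volume, rep(V / 8, 8), tolerance = 1e-12)

  # volume conservation at random configurations, small and large
  for (n in c(17, 300, 2000)) {
    set.seed(n)
    vr <- voronoi_volumes(runif_positions(n, dom), dom)
    expect_lt(abs(sum(vr$volume) - V) / V, 1e-6)
    expect_true(all(vr$volume > 0))
  }

  # errors: empty input, duplicate generators
  expect_error(voronoi_volumes(matrix(0, 0, 3), dom), "empty")
  P <- runif_positions(5, dom)
  expect_error(voronoi_volumes(rbind(P, P[2, ]), dom), "duplicate")
})

test_that("Voronoi volumes agree with a grid-counting oracle", {
  dom <- flow_domain()
  set.seed(7)
  P <- runif_positions(50, dom)
  vols <- voronoi_volumes(P, dom)$volume
  oracle <- voronoi_grid_oracle(P, dom, n = 200L)
  expect_true(all(abs(vols - oracle) / vols < 0.02))
})

test_that("concentration is the inverse volume and conserves total volume", {
  dom <- flow_domain()
  vr <- local_concentration(voronoi_volumes(matrix(c(0.3, 0.3, 0.15), 1), dom))
  expect_equal(vr$concentration, 1 / 0.108, tolerance = 1e-12)

  set.seed(12)
  vr <- local_concentration(voronoi_volumes(runif_positions(80, dom), dom))
  expect_equal(sum(1 / vr$concentration), 0.108, tolerance = 1e-9)
})

test_that("patch selection takes the top f by concentration with stable ties", {
  expect_equal(select_patches(c(3, 1, 2), f = 1), 1:3)
  set.seed(1)
  conc <- runif(100)
  expect_equal(select_patches(conc, f = 0.01), which.max(conc))
  expect_equal(select_patches(1:100, f = 0.05), 96:100)
  # ties: earlier index wins
  expect_equal(select_patches(c(5, 5, 5, 1), f = 0.5), c(1, 2))
  # partition property and monotone patch threshold as f decreases
  sel10 <- select_patches(conc, 0.10)
  sel05 <- select_patches(conc, 0.05)
  expect_true(all(sel05 %in% sel10))
  expect_gte(min(conc[sel05]), min(conc[sel10]))
})

test_that("Q statistic follows its defining arithmetic and sign convention", {
  expect_equal(q_statistic(c(1, 2, 3), c(1, 2, 3), C_M = 5), 0)
  expect_equal(q_statistic(rep(2, 5), rep(1, 5), C_M = 1), 1)
  # negative Q is legal: depleted motile patches
  expect_equal(q_statistic(0.6 * 7, 1.3 * 7, C_M = 7), -0.7)
  expect_true(is.na(q_statistic(numeric(), c(1), C_M = 1)))
})

test_that("Q series is zero for identical ensembles and antisymmetric under swap", {
  set.seed(21)
  dom <- flow_domain()
  X <- runif_positions(800, dom, z_range = c(0.1, 0.29))
  trA <- snapshot_trajectory(X, times = c(0, 1))
  trB <- snapshot_trajectory(runif_positions(800, dom, z_range = c(0.1, 0.29)),
                             times = c(0, 1))
  qAA <- q_timeseries_by_region(trA, trA)
  expect_true(all(qAA$Q[!is.na(qAA$Q)] == 0))

  qAB <- q_timeseries_by_region(trA, trB)
  qBA <- q_timeseries_by_region(trB, trA)
  expect_equal(qAB$Q, -qBA$Q)

  # invariance under rigid horizontal translation of both ensembles
  shift <- function(X) cbind((X[, 1] + 0.21) %% 0.6, (X[, 2] + 0.47) %% 0.6, X[, 3])
  qAB2 <- q_timeseries_by_region(snapshot_trajectory(shift(X), times = c(0, 1)),
                                 snapshot_trajectory(shift(trB$X[1, , ]), times = c(0, 1)))
  expect_equal(qAB2$Q, qAB$Q, tolerance = 1e-9)

  expect_error(q_timeseries_by_region(trA, snapshot_trajectory(X, times = c(0, 2))),
               "share")
})

test_that("a planted dense cluster yields positive deep Q matching a direct evaluation", {
  dom <- flow_domain()
  z_excl <- 0.3 - 0.3 / 360
  set.seed(33)
  n_bg <- 2850; n_cl <- 150
  bg <- runif_positions(n_bg, dom)
  # cluster in the Deep bin with ~3x the mean concentration
  cl <- cbind(runif(n_cl, 0.2, 0.4), runif(n_cl, 0.2, 0.4), runif(n_cl, 0.11, 0.155))
  motile <- rbind(bg, cl)
  motile <- motile[motile[, 3] <= z_excl, ]
  nonmotile <- runif_positions(3000, dom)
  nonmotile <- nonmotile[nonmotile[, 3] <= z_excl, ]

  tr_m <- snapshot_trajectory(motile, times = 0,
                              motility = motility_params("gyrotactic", B = 1, v_swim = 1e-4))
  tr_n <- snapshot_trajectory(nonmotile, times = 0)
  qs <- q_timeseries_by_region(tr_m, tr_n, f = 0.02, cadence = 1)

  q_deep <- qs$Q[qs$region == "Deep"]
  q_shallow <- qs$Q[qs$region == "Shallow"]
  expect_gt(q_deep, 0.5)

  # direct evaluation of the defining formula, independently of the series code
  f <- 0.02
  conc_m <- 1 / voronoi_volumes(motile, dom)$volume
  conc_n <- 1 / voronoi_volumes(nonmotile, dom)$volume
  top_m <- order(conc_m, decreasing = TRUE)[seq_len(ceiling(f * length(conc_m)))]
  top_n <- order(conc_n, decreasing = TRUE)[seq_len(ceiling(f * length(conc_n)))]
  in_deep <- function(z) z >= 0.10 & z < 0.17
  C_M <- nrow(tr_m$X[1, , , drop = FALSE][1, , ]) / (0.6 * 0.6 * z_excl)
  C_M <- nrow(motile) / (0.6 * 0.6 * z_excl)
  q_hand <- (median(conc_m[top_m][in_deep(motile[top_m, 3])]) -
             median(conc_n[top_n][in_deep(nonmotile[top_n, 3])])) / C_M
  expect_equal(q_deep, q_hand, tolerance = 1e-12)
  # same direct evaluation away from the cluster: the shallow bin carries
  # order-statistic noise only, reproduced exactly by the pipeline
  in_shallow <- function(z) z >= 0.24 & z <= 0.30
  q_hand_sh <- (median(conc_m[top_m][in_shallow(motile[top_m, 3])]) -
                median(conc_n[top_n][in_shallow(nonmotile[top_n, 3])])) / C_M
  if (!is.na(q_shallow)) expect_equal(q_shallow, q_hand_sh, tolerance = 1e-12)
})

test_that("truncated-time mean Q equals the prefix mean of the full series", {
  set.seed(8)
  dom <- flow_domain()
  nt <- 6
  Xs <- lapply(1:nt, function(i) runif_positions(400, dom, c(0.1, 0.29)))
  mk_traj <- function(Xlist) {
    n <- 400
    Xa <- array(NA_real_, c(nt, n, 3)); Pa <- array(0, c(nt, n, 3)); Pa[, , 3] <- 1
    for (i in 1:nt) Xa[i, , ] <- Xlist[[i]]
    cfg <- simulation_config(n_microbes = n, total_time = nt - 1, output_interval = 1)
    structure(list(times = 0:(nt - 1), X = Xa, P = Pa,
                   motility = motility_params("non_motile"), config = cfg,
                   seed = 0L, domain = dom), class = "gp_trajectory")
  }
  trA <- mk_traj(Xs)
  trB <- mk_traj(lapply(1:nt, function(i) runif_positions(400, dom, c(0.1, 0.29))))
  qs <- q_timeseries_by_region(trA, trB, regions = NULL)
  full_means <- q_mean(qs, t_max = 3)
  prefix <- mean(qs$Q[qs$time <= 3], na.rm = TRUE)
  expect_equal(full_means$Q_mean, prefix)
})

test_that("patch concentration distributions separate planted clusters from uniform", {
  dom <- flow_domain()
  set.seed(44)
  unif <- runif_positions(2000, dom, c(0.1, 0.29))
  tr_u <- snapshot_trajectory(unif, times = 0)
  pd_u <- patch_concentration_distribution(tr_u, regions = NULL, f = 0.05,
                                           window = c(0, 0))
  # uniform: patch concentrations are bounded above the mean but not extreme
  C_M <- 2000 / (0.6 * 0.6 * (0.3 - 0.3 / 360))
  expect_gt(pd_u$summary$median, C_M)          # patches are denser than average
  expect_lt(pd_u$summary$cv, 1)                # but not heavy-tailed for uniform

  cl <- rbind(unif, cbind(runif(300, 0.2, 0.25), runif(300, 0.2, 0.25),
                          runif(300, 0.12, 0.16)))
  pd_c <- patch_concentration_distribution(snapshot_trajectory(cl, times = 0),
                                           regions = NULL, f = 0.05,
                                           window = c(0, 0))
  expect_gt(pd_c$summary$q95, pd_u$summary$q95)

  # window outside the span yields a missing summary, not an error
  pd_m <- patch_concentration_distribution(tr_u, window = c(5, 6))
  expect_true(all(is.na(pd_m$summary$median)))
})
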