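# helper: quick 3-body assembly with fit libraries built from the truth
# plus decoy entries, so recombination has real work to do
three_body_setup <- function(seed = 2, n_links = 20, decoy = 0.05) {
  truth <- generate_assembly(3, body_size = c(150, 100, 70), seed = seed,
                             gap = 8)
  map <- simulate_noisy_map(truth, resolution = 25, noise_sd = 0.05,
                            voxel = 4, seed = seed)
  map$resolution <- 25
  xl <- simulate_crosslinks(truth, n_links, decoy_fraction = decoy,
                            reach = 30, seed = seed)
  libs <- list()
  for (nm in names(truth$bodies)) {
    bm <- body_model(truth$model, truth$bodies[[nm]])
    libs[[nm]] <- global_fit(bm, map, n_starts = 120, n_opt_steps = 120,
                             seed = seed + match(nm, names(truth$bodies)),
                             max_fits = 40)
  }
  list(truth = truth, map = map, xl = xl, libs = libs)
}

.three_body <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- three_body_setup()
    cache
  }
})

test_that("at low temperature a single body adopts its best fit", {
  case <- small_body_case()
  lib <- global_fit(case$body, case$map, n_starts = 40, n_opt_steps = 60,
                    seed = 3, max_fits = 10)
  cfgs <- sample_configurations(list(b = lib), case$truth$model,
                                setNames(case$truth$bodies, "b"),
                                crosslinks = NULL, n_configs = 10,
                                n_steps = 300, T0 = 0.05, T1 = 1e-4,
                                seed = 5)
  for (cf in cfgs) expect_equal(unname(cf$indices["b"]), 1L)
})

test_that("recombination recovers a 3-body ground truth with a decoy", {
  s <- .three_body()
  cfgs <- sample_configurations(s$libs, s$truth$model, s$truth$bodies,
                                s$xl, n_configs = 40, n_steps = 1500,
                                seed = 11)
  errs <- assignment_errors(cfgs[[1]], s$truth)
  expect_true(all(errs$trans_err < 10))
})

test_that("recombination is reproducible and improves with more steps", {
  s <- .three_body()
  a <- sample_configurations(s$libs, s$truth$model, s$truth$bodies, s$xl,
                             n_configs = 5, n_steps = 400, seed = 7)
  b <- sample_configurations(s$libs, s$truth$model, s$truth$bodies, s$xl,
                             n_configs = 5, n_steps = 400, seed = 7)
  expect_identical(lapply(a, `[[`, "indices"), lapply(b, `[[`, "indices"))
  expect_equal(sapply(a, function(cf) cf$score$total),
               sapply(b, function(cf) cf$score$total))

  # stochastic improvement: median best-of-run total at many steps is
  # no worse than at few steps
  few <- sample_configurations(s$libs, s$truth$model, s$truth$bodies,
                               s$xl, n_configs = 15, n_steps = 60,
                               seed = 13)
  many <- sample_configurations(s$libs, s$truth$model, s$truth$bodies,
                                s$xl, n_configs = 15, n_steps = 2000,
                                seed = 13)
  expect_lte(median(sapply(many, function(cf) cf$score$total)),
             median(sapply(few, function(cf) cf$score$total)))
})

test_that("serialized configurations rescore to their stored totals", {
  s <- .three_body()
  cfgs <- sample_configurations(s$libs, s$truth$model, s$truth$bodies,
                                s$xl, n_configs = 3, n_steps = 500,
                                seed = 19)
  path <- withr::local_tempfile(fileext = ".json")
  write_configuration(cfgs[[1]], path)
  back <- read_configuration(path)
  expect_equal(back$score$total, cfgs[[1]]$score$total)
  # recomputing the score from the deserialized indices is exact
  pre <- rigidem:::precompute_assembly(s$libs, s$truth$model,
                                       s$truth$bodies, s$xl)
  sc <- rigidem:::cpp_score_indices(
    unname(back$indices[pre$body_names]) - 1L, pre$tr_pts, pre$tr_beads,
    pre$nccs, pre$radii, pre$cand, pre$cand_link, pre$conn, pre$conn_max,
    c(60, 1, 1, 0.1), 30, 3, 3, 9)
  expect_equal(unname(sc["total"]), back$score$total, tolerance = 1e-9)
})

test_that("continuous refinement never worsens and re-centers a shift", {
  case <- two_body_case(seed = 41)
  map <- case$map
  map$resolution <- 25
  truth <- case$truth
  # an already-correct configuration stays within 1% of its score
  start <- truth$poses_true
  r0 <- refine_continuous(start, map, truth$model, truth$bodies,
                          crosslinks = NULL, n_steps = 1, seed = 1)
  r1 <- refine_continuous(start, map, truth$model, truth$bodies,
                          crosslinks = NULL, n_steps = 400, seed = 1)
  expect_lte(r1$score$total, r0$score$total + 1e-9)
  expect_lt(abs(r1$score$total - r0$score$total),
            0.01 * abs(r0$score$total))

  # a 5 A displacement refines back to under 2 A centroid error
  shifted <- truth$poses_true
  shifted[[1]]$t <- shifted[[1]]$t + c(5, 0, 0)
  ref <- refine_continuous(shifted, map, truth$model, truth$bodies,
                           crosslinks = NULL, n_steps = 1500,
                           trans_step = 2, seed = 3)
  errs <- pose_errors(ref, truth)
  expect_lt(errs$trans_err[1], 2)

  # fixed seed gives a bit-identical trajectory
  ref2 <- refine_continuous(shifted, map, truth$model, truth$bodies,
                            crosslinks = NULL, n_steps = 1500,
                            trans_step = 2, seed = 3)
  expect_identical(ref$poses, ref2$poses)
})

test_that("hinge splitting yields two lobes joined by the hinge linker", {
  m <- line_model(100)
  split <- segment_rigid_bodies(m, data.frame(
    body = c("lobe1", "lobe2"), chain = "A",
    start = c(1, 61), end = c(45, 100)))
  expect_equal(split$lobe1$linker_neighbors$n_linker, 15L)

  # null-change control: splitting and refitting an unchanged map
  # reproduces the unsplit pose within one voxel
  case <- two_body_case(seed = 51)
  map <- case$map
  map$resolution <- 25
  # one chain spanning both bodies so the hinge sits inside it
  at <- case$truth$model$atoms
  n1 <- sum(at$chain == names(case$truth$bodies)[1] |
              at$chain == "A")
  joined <- at
  joined$resno[joined$chain == "B"] <-
    joined$resno[joined$chain == "B"] + max(at$resno[at$chain == "A"]) + 12
  joined$chain <- "A"
  jm <- atomic_model(joined)
  hinge <- c(max(at$resno[at$chain == "A"]) + 1,
             max(at$resno[at$chain == "A"]) + 11)
  res <- hinge_split_refit(jm, hinge, "A", map, n_starts = 150,
                           n_opt_steps = 150, seed = 6, refine_steps = 300)
  expect_length(res$bodies, 2L)
  expect_equal(res$bodies$lobe1$linker_neighbors$n_linker, 11L)
  for (b in names(res$config$poses)) {
    expect_lt(sqrt(sum(res$config$poses[[b]]$t^2)), map$voxel)
  }
  expect_error(hinge_split_refit(jm, c(1, 5), "A", map), "inside")
})

test_that("rebuilding applies poses rigidly and bridges linkers", {
  case <- two_body_case(seed = 61)
  truth <- case$truth
  ident <- lapply(truth$poses_true[names(truth$bodies)],
                  function(p) list(q = c(1, 0, 0, 0), t = c(0, 0, 0)))
  out <- rebuild_full_model(ident, truth$model, truth$bodies)
  expect_equal(out$atoms, truth$model$atoms, tolerance = 1e-12)

  # per-body RMSD between rebuilt and pose-transformed original is 0
  R <- axis_angle_matrix(c(0, 1, 0), 0.5)
  poses <- ident
  poses[[1]] <- list(q = rigidem:::matrix_to_quat(R), t = c(10, 5, -3))
  out2 <- rebuild_full_model(poses, truth$model, truth$bodies)
  b1 <- names(truth$bodies)[1]
  got <- ca_xyz(calpha(body_model(out2, truth$bodies[[b1]])))
  ref <- ca_xyz(calpha(body_model(truth$model, truth$bodies[[b1]])))
  c0 <- colMeans(ref)
  want <- sweep(sweep(ref, 2, c0) %*% t(R), 2, c0 + c(10, 5, -3), "+")
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)

  # linker residues are interpolated: consecutive CA gaps stay bonded
  at <- line_model(60)$atoms
  m <- atomic_model(at)
  bodies <- segment_rigid_bodies(m, data.frame(
    body = c("n", "c"), chain = "A", start = c(1, 41), end = c(30, 60)))
  poses2 <- list(n = list(q = c(1, 0, 0, 0), t = c(0, 0, 0)),
                 c = list(q = c(1, 0, 0, 0), t = c(0, 0, 6)))
  out3 <- rebuild_full_model(poses2, m, bodies)
  ca <- calpha(out3)
  gaps <- sqrt(rowSums(diff(as.matrix(ca[, c("x", "y", "z")]))^2))
  expect_true(all(gaps <= 4.5))
})
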