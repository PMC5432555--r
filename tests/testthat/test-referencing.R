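test_that("simple transforms match their defining matrices", {
  lay <- make_layout(21)
  n <- 21
  # DLM on a 3-channel toy: rows a=3, m1=1, m2=3 -> 1, -1, 1
  toy <- structure(list(names = c("a", "m1", "m2"),
                        positions = diag(3) * 0.092, mastoid_pair = c("m1", "m2"),
                        vertex = "a", density_tag = NA_integer_, radius = 0.092,
                        center = c(0, 0, 0)), class = "electrode_layout")
  Tdlm <- make_simple_transform("DLM", toy)$matrix
  V <- matrix(c(3, 1, 3), 3, 4)
  expect_equal(unname(Tdlm %*% V), matrix(c(1, -1, 1), 3, 4))
  # AVE annihilates the channel mean at every sample
  Tave <- make_simple_transform("AVE", lay)$matrix
  set.seed(1)
  V <- matrix(rnorm(n * 50), n, 50)
  expect_lt(max(abs(colMeans(Tave %*% V))), 1e-12)
  # data already referenced to Cz are left untouched by the Cz transform
  Tcz <- make_simple_transform("Cz", lay)$matrix
  Vcz <- V
  Vcz[match("Cz", lay$names), ] <- 0
  expect_equal(unname(Tcz %*% Vcz), unname(Vcz))
})

test_that("simple transforms are idempotent and annihilate common offsets", {
  lay <- make_layout(34)
  for (scheme in c("Cz", "DLM", "AVE")) {
    Tm <- make_simple_transform(scheme, lay)$matrix
    expect_lt(max(abs(rowSums(Tm))), 1e-12)          # kills the all-ones vector
    expect_lt(max(abs(Tm %*% Tm - Tm)), 1e-10)       # T^2 = T
  }
  # reference-start independence: T_X T_Cz = T_X for X in {AVE, DLM}
  Tcz <- make_simple_transform("Cz", lay)$matrix
  for (scheme in c("AVE", "DLM")) {
    Tx <- make_simple_transform(scheme, lay)$matrix
    expect_lt(max(abs(Tx %*% Tcz - Tx)), 1e-12)
  }
})

test_that("transforms apply linearly and update recording metadata", {
  m <- test_model()
  lay <- make_layout(21, m)
  grid <- get_cached("grid5mm", function() source_grid(m, 0.005))
  rec <- gen_dataset(test_cfg(duration = 4, seed = 13), lay, m, grid = grid)
  Tave <- make_simple_transform("AVE", lay)
  out <- apply_transform(Tave, rec)
  expect_identical(out$reference, "AVE")
  expect_equal(out$data, Tave$matrix %*% rec$data, ignore_attr = TRUE)
  # identity transform leaves the data unchanged
  Tid <- ref_transform(diag(21), "REST")
  expect_equal(apply_transform(Tid, rec)$data, rec$data, ignore_attr = TRUE)
  # linearity
  rec2 <- rec; rec2$data <- rec$data^2 / max(abs(rec$data))
  lin <- 2 * (Tave$matrix %*% rec$data) - 3 * (Tave$matrix %*% rec2$data)
  mix <- rec; mix$data <- 2 * rec$data - 3 * rec2$data
  expect_equal(apply_transform(Tave, mix)$data, lin, tolerance = 1e-12,
               ignore_attr = TRUE)
  # dimension mismatch
  expect_error(apply_transform(ref_transform(diag(5), "AVE"), rec), "disagree")
})

test_that("ESD surface has the configured size, unit normals and quasi-uniform spacing", {
  m <- test_model()
  esd <- build_esd(m, 4000)
  expect_identical(nrow(esd$positions), 4000L)
  expect_equal(sqrt(rowSums(esd$orientations^2)), rep(1, 4000), tolerance = 1e-9)
  r <- sqrt(rowSums(esd$positions^2))
  expect_true(all(r < m$radii[1]))
  # nearest-neighbour spacing: coefficient of variation < 0.5
  sub <- esd$positions[seq(1, 4000, by = 8), ]
  d <- as.matrix(dist(sub))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.5)
  expect_error(build_esd(m, 50), "count")
  expect_error(build_esd(m, 500, cap_angle_deg = 200), "cap_angle")
})

test_that("REST is deterministic and suppresses pure reference offsets", {
  m <- test_model()
  lay <- make_layout(21, m)
  esd <- get_cached("esd2000", function() build_esd(m, 2000))
  T1 <- make_rest_transform(lay, m, esd)
  T2 <- make_rest_transform(lay, m, esd)
  expect_identical(T1$matrix, T2$matrix)
  expect_identical(T1$scheme, "REST")
  # an all-ones column (pure reference offset) is strongly suppressed
  ones <- matrix(1, 21, 10)
  expect_lt(norm(T1$matrix %*% ones, "F") / norm(ones, "F"), 0.5)
})

test_that("REST recovers infinity-referenced ESD data where the problem is well-posed", {
  set.seed(201)
  m <- test_model()
  # dense whole-sphere covering: the common offset is then identifiable
  # because external fields integrate to zero over a closed surface
  lay <- whole_sphere_layout(64, m)
  esd <- get_cached("esd2000", function() build_esd(m, 2000))
  G <- leadfield(esd, lay, m)
  act <- matrix(rnorm(2000 * 300), 2000, 300)
  Vinf <- G %*% act
  Tcz <- diag(64); Tcz[, 1] <- Tcz[, 1] - 1   # reference to one electrode
  Tr <- suppressMessages(make_rest_transform(lay, m, esd,
                                             acquisition_reference = "Cz"))
  # build the acquisition transform consistent with the layout vertex (S1)
  Vrest <- Tr$matrix %*% (Tcz %*% Vinf)
  expect_lt(norm(Vrest - Vinf, "F") / norm(Vinf, "F"), 0.01)
})

test_that("at a standard montage REST recovers the spatial pattern; the residual is a common offset", {
  set.seed(202)
  m <- test_model()
  lay <- make_layout(21, m)
  esd <- get_cached("esd2000", function() build_esd(m, 2000))
  G <- leadfield(esd, lay, m)
  Vinf <- G %*% matrix(rnorm(2000 * 100), 2000, 100)
  Tcz <- make_simple_transform("Cz", lay)$matrix
  Tr <- suppressMessages(make_rest_transform(lay, m, esd))
  err <- Tr$matrix %*% (Tcz %*% Vinf) - Vinf
  # per-sample deviation from a channel-constant residual: machine level
  centred <- sweep(err, 2, colMeans(err))
  expect_lt(norm(centred, "F") / norm(Vinf, "F"), 1e-10)
})

test_that("REST degrades strictly under head-model mismatch", {
  set.seed(203)
  m <- test_model()
  lay <- make_layout(21, m)
  esd <- get_cached("esd2000", function() build_esd(m, 2000))
  G <- leadfield(esd, lay, m)
  Vinf <- G %*% matrix(rnorm(2000 * 200), 2000, 200)
  Tcz <- make_simple_transform("Cz", lay)$matrix
  recover_err <- function(mod) {
    Tr <- suppressMessages(make_rest_transform(lay, mod,
                                               esd = build_esd(mod, 2000)))
    norm(Tr$matrix %*% (Tcz %*% Vinf) - Vinf, "F") / norm(Vinf, "F")
  }
  e0 <- recover_err(m)
  # skull conductivity misassumed by growing factors: error strictly grows
  e_up <- vapply(c(1.5, 2, 3), function(sf)
    recover_err(perturb_model(m, 1.0, sf)), numeric(1))
  expect_true(all(diff(c(e0, e_up)) > 0))
  # and in the other direction (-50%)
  expect_gt(recover_err(perturb_model(m, 1.0, 0.5)), e0)
})
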