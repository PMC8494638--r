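ctx <- layer_context()

test_that("SWC round trip is the identity on valid trees", {
  toy <- "1 1 0 -300 0 8 -1\n2 4 0 -200 0 2 1\n3 3 10 -310 0 1 1\n"
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(toy, f)
  m <- read_swc(f)
  expect_identical(nrow(m), 3L)
  expect_identical(sum(m$parent == -1), 1L)
  expect_identical(m$type, c("soma", "apical", "basal"))
  for (s in 1:3) {
    m0 <- simulate_morphology(sample(c("superficial", "deep"), 1),
                              runif(1, 350, 1100), ctx, seed = s)
    f2 <- withr::local_tempfile(fileext = ".swc")
    write_swc(m0, f2)
    m1 <- read_swc(f2)
    for (col in c("id", "x", "y", "z", "radius", "parent"))
      expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
    expect_identical(m1$type, m0$type)
  }
})

test_that("malformed SWC inputs are rejected, unknown types preserved", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 8 -1\n2 3 5 -5 0 1 2\n", f)   # own parent
  expect_error(read_swc(f), "cycle|parent")
  writeLines("1 1 0 0 0 8 -1\n2 7 5 -5 0 1 1\n", f)   # unknown code 7
  expect_warning(m <- read_swc(f), "unknown")
  expect_identical(m$type[2], "7")
  writeLines("1 1 0 0 0 8 -1\n2 3 5 -5 0 1 99\n", f)  # dangling parent
  expect_error(read_swc(f), "parent")
})

test_that("shrinkage correction scales z about the soma only", {
  m <- simulate_morphology("deep", 800, ctx, seed = 1)
  expect_equal(correct_shrinkage(m, 40, 40)$z, m$z, tolerance = 1e-12)
  m2 <- correct_shrinkage(m, 60, 30)
  soma_z <- m$z[m$parent == -1]
  expect_equal(m2$z - soma_z, (m$z - soma_z) * 2, tolerance = 1e-9)
  expect_identical(m2$x, m$x)
  expect_identical(m2$y, m$y)
  expect_equal(m2$z[m$parent == -1], soma_z)          # soma is a fixed point
  expect_error(correct_shrinkage(m, 0, 30), "positive")
})

test_that("tilt correction is a rigid rotation about the soma", {
  m <- simulate_morphology("superficial", 500, ctx, seed = 2)
  expect_equal(correct_tilt(m, 0)$y, m$y)
  expect_error(correct_tilt(m, 90), "range")
  soma <- c(m$x[1], m$y[1], m$z[1])
  d0 <- sqrt((m$x - soma[1])^2 + (m$y - soma[2])^2 + (m$z - soma[3])^2)
  m2 <- correct_tilt(m, 17.3)
  d1 <- sqrt((m2$x - soma[1])^2 + (m2$y - soma[2])^2 + (m2$z - soma[3])^2)
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("laminar histogram conserves length and splits segments by
          interpolation", {
  # single vertical 100 um apical segment inside one 50 um bin:
  # depth 110 -> 100 goes to bin (100, 150]... use bins of 200 um
  nodes <- data.frame(
    id = 1:3, type = c("soma", "apical", "apical"),
    x = 0, y = c(-400, -390, -290), z = 0, radius = c(8, 2, 2),
    parent = c(-1, 1, 2))
  m <- morphology(nodes)
  h <- laminar_histogram(m, "apical", ctx, bin_um = 200)
  # the 100 um segment spans depths 290-390, inside the (200, 400] bins:
  # 110/100 split between (200,400)? depths 290..390 lie inside bin 2
  expect_equal(sum(h$bins$length_um), h$total_um, tolerance = 1e-12)
  expect_equal(h$bins$length_um[2], 100 + 10, tolerance = 1e-9)
  # segment straddling a bin edge at its midpoint splits 50/50
  nodes2 <- data.frame(
    id = 1:2, type = c("soma", "basal"),
    x = 0, y = c(-380, -420), z = 0, radius = c(8, 1), parent = c(-1, 1))
  h2 <- laminar_histogram(morphology(nodes2), "basal", ctx, bin_um = 400)
  expect_equal(h2$bins$length_um[1], 20, tolerance = 1e-9)
  expect_equal(h2$bins$length_um[2], 20, tolerance = 1e-9)
  expect_error(laminar_histogram(m, "apical", ctx = "x"), "layer_context")
})

test_that("histogram equals the fine-subdivision oracle within 0.1%", {
  for (s in 1:5) {
    m <- simulate_morphology(sample(c("superficial", "deep"), 1),
                             runif(1, 320, 1150), ctx, seed = 100 + s)
    for (comp in c("apical", "basal")) {
      got <- laminar_histogram(m, comp, ctx, bin_um = 50)$bins$length_um
      want <- oracle_hist_fine(m, comp, ctx, bin_um = 50, piece_um = 0.25)
      total <- oracle_total_length(m, comp)
      expect_lt(max(abs(got - want[seq_along(got)])) / total, 1e-3)
      expect_equal(sum(got), total, tolerance = 1e-9)
    }
  }
})

test_that("length is conserved under tilt rotation", {
  m <- simulate_morphology("deep", 700, ctx, seed = 6)
  before <- oracle_total_length(m)
  m2 <- correct_tilt(m, -12)
  expect_equal(oracle_total_length(m2), before, tolerance = 1e-9)
})

test_that("morphometrics match constructive ground truth and oracles", {
  for (s in 1:5) {
    arch <- sample(c("superficial", "deep"), 1)
    m <- simulate_morphology(arch, runif(1, 320, 1150), ctx, seed = 200 + s)
    gt <- attr(m, "ground_truth")
    mm <- morphometrics(m, ctx)
    expect_equal(mm$apical_height_um, gt$apical_extent_um,
                 tolerance = 0.01)
    expect_equal(mm$basal_max_distance_um, gt$basal_max_distance_um,
                 tolerance = 1e-9)
    expect_identical(mm$basal_max_distance_um, oracle_basal_max(m))
    l1 <- laminar_histogram(m, "apical", ctx)$layers[["L1"]]
    if (arch == "deep") expect_identical(l1, 0)
    else expect_gt(l1, 0)
  }
})

test_that("archetypes place the apical tip on the right side of L1", {
  sup <- simulate_morphology("superficial", 300, ctx, seed = 11)
  ap <- sup[sup$type == "apical", ]
  expect_lt(min(-ap$y), ctx$boundaries[["l12"]])    # tip above L1/2
  deep <- simulate_morphology("deep", 900, ctx, seed = 12)
  apd <- deep[deep$type == "apical", ]
  expect_gt(min(-apd$y), ctx$boundaries[["l12"]])   # never enters L1
  expect_error(simulate_morphology("deep", 100, ctx), "L2-L3")
})

test_that("a straight unbranched dendrite has branch order 1", {
  nodes <- data.frame(
    id = 1:4, type = c("soma", rep("basal", 3)),
    x = c(0, 10, 20, 30), y = -500, z = 0,
    radius = c(8, 1, 1, 1), parent = c(-1, 1, 2, 3))
  mm <- morphometrics(morphology(nodes), ctx)
  expect_identical(mm$max_branch_order, 1L)
  expect_true(is.na(mm$apical_height_um))  # missing compartment, not error
})

test_that("apical histogram PC0 separates L1-rich from L1-poor cells", {
  lay <- c("L1", "L2-3", "L4")
  h <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  colnames(h) <- lay
  sc <- apical_hist_pc0(h)
  expect_gt(sc[1], 0)                      # L1-dominated: positive score
  expect_lt(sc[3], 0)
  expect_equal(sc[1], sc[2])
  # degenerate cohort: all scores zero
  hd <- matrix(rep(c(0.3, 0.6, 0.1), 4), 4, byrow = TRUE,
               dimnames = list(NULL, lay))
  expect_identical(apical_hist_pc0(hd), rep(0, 4))
  expect_error(apical_hist_pc0(h[1:2, ]), ">= 3")
  expect_error(apical_hist_pc0(h * 2), "unit sum")
  # recovery: scores track a designed L1 fraction
  set.seed(3)
  f <- runif(20)
  hm <- cbind(L1 = f, `L2-3` = (1 - f) * 0.7, L4 = (1 - f) * 0.3)
  expect_gt(abs(cor(apical_hist_pc0(hm), f)), 0.9)
})

test_that("morphology validation catches structural defects", {
  bad <- data.frame(id = 1:2, type = c("soma", "basal"), x = 0, y = 0,
                    z = 0, radius = 1, parent = c(-1, -1))
  expect_error(morphology(bad), "disconnected")
  two_somas <- data.frame(id = 1:2, type = "soma", x = 0, y = 0, z = 0,
                          radius = 8, parent = c(-1, -1))
  expect_error(morphology(two_somas), "exactly one soma")
})
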