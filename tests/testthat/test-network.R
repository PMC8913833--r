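toy_table <- function(values) {
  # values: named list metabolite -> length-n concentration vector
  n <- length(values[[1L]])
  tibble::tibble(
    group = "g",
    subject = rep(sprintf("g_%02d", seq_len(n)), times = length(values)),
    time_point = 1L,
    metabolite = rep(names(values), each = n),
    concentration = unlist(values, use.names = FALSE),
    crlb = 5)
}

test_that("spearman_matrix reproduces the rank-formula oracle on toy data", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  tab <- toy_table(list(A = x, B = y))
  m <- spearman_matrix(tab, "g", 1)
  expect_equal(m$values["A", "B"], abs(spearman_rank_formula(x, y)))
  expect_equal(m$values["A", "B"], 0.8)
  expect_identical(unname(diag(m$values)), c(0, 0))
})

test_that("perfectly concordant and reversed rankings both give |rho| = 1", {
  tab <- toy_table(list(A = 1:6, B = exp(1:6), C = 6:1))
  m <- spearman_matrix(tab, "g", 1)$values
  expect_equal(m["A", "B"], 1)   # concordant
  expect_equal(m["A", "C"], 1)   # reversed, absolute value
  expect_identical(m, t(m))
})

test_that("spearman_matrix is invariant to monotone transforms and subject order", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- list(A = rlnorm(8), B = rlnorm(8), C = rlnorm(8), D = rlnorm(8))
    tab <- toy_table(vals)
    base <- spearman_matrix(tab, "g", 1)$values
    warped <- toy_table(list(A = exp(vals$A), B = vals$B^3,
                             C = atan(vals$C), D = vals$D * 7 + 2))
    expect_equal(spearman_matrix(warped, "g", 1)$values, base)
    shuffled <- tab[sample(nrow(tab)), ]
    shuffled_vals <- spearman_matrix(shuffled, "g", 1)$values
    # row shuffling may reorder the panel; align before comparing
    expect_equal(shuffled_vals[rownames(base), colnames(base)], base)
  }
})

test_that("zero-variance metabolites warn and contribute no edges", {
  tab <- toy_table(list(A = 1:5, B = c(2, 1, 4, 3, 5), K = rep(3, 5)))
  expect_warning(m <- spearman_matrix(tab, "g", 1), "zero-variance")
  expect_true(all(m$values["K", ] == 0))
})

test_that("spearman_matrix requires at least 3 subjects", {
  tab <- toy_table(list(A = 1:2, B = 2:1))
  expect_error(spearman_matrix(tab, "g", 1), "3 subjects")
})

test_that("binarize uses a strict threshold and validates input", {
  vals <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  vals["a", "b"] <- vals["b", "a"] <- 0.45
  vals["b", "c"] <- vals["c", "b"] <- 0.41
  m <- metabnet:::new_correlation_matrix(vals, "g", 1, letters[1:3])
  net <- binarize(m, 0.41)
  expect_equal(net$adjacency["a", "b"], 1L)   # above the threshold
  expect_equal(net$adjacency["b", "c"], 0L)   # exactly at the threshold
  expect_equal(sum(binarize(m, 0.99)$adjacency), 0L)  # everything below
  expect_error(binarize(m, 1), "threshold")
  expect_error(binarize(m, -0.1), "threshold")
})

test_that("threshold sweeps are nested and match element-wise binarization", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- matrix(0, 11, 11)
    vals[upper.tri(vals)] <- runif(55)
    vals <- vals + t(vals)
    dimnames(vals) <- list(default_panel(), default_panel())
    m <- metabnet:::new_correlation_matrix(vals, "g", 1, default_panel())
    nets <- threshold_sweep(m)
    expect_length(nets, 9)
    for (k in seq_along(nets)) {
      expect_identical(nets[[k]]$adjacency,
                       {a <- (vals > default_thresholds()[k]) * 1L
                        diag(a) <- 0L; storage.mode(a) <- "integer"; a})
      if (k > 1) {
        expect_true(all(nets[[k]]$adjacency <= nets[[k - 1]]$adjacency))
      }
    }
  }
  expect_error(threshold_sweep(m, numeric()), "non-empty")
  expect_error(threshold_sweep(m, c(0.3, 0.2)), "increasing")
})

test_that("backbone sign test matches the binomial closed form at T = 8", {
  panel <- c("A", "B", "C")
  mk <- function(ab) {
    vals <- matrix(0, 3, 3, dimnames = list(panel, panel))
    vals["A", "B"] <- vals["B", "A"] <- ab
    vals["A", "C"] <- vals["C", "A"] <- 0.5
    metabnet:::new_correlation_matrix(vals, "g", 1, panel)
  }
  # A-B present at all 8 time points: p = 0.5^8 < 0.025 -> eligible
  mats <- rep(list(mk(0.6)), 8)
  bb <- backbone(mats)
  expect_equal(bb$sign_test_p["A", "B"], 0.5^8)
  expect_true(bb$eligible["A", "B"])
  # present at 7 of 8: p = 9/256 > 0.025 -> not eligible
  mats7 <- c(rep(list(mk(0.6)), 7), list(mk(0)))
  bb7 <- backbone(mats7)
  expect_equal(bb7$sign_test_p["A", "B"], 9 / 256)
  expect_false(bb7$eligible["A", "B"])
  expect_equal(bb7$matrix$values["A", "B"], 0)
  expect_equal(bb$alpha, 0.025)
})

test_that("backbone aggregates eligible pairs by the minimum across time", {
  panel <- c("A", "B", "C")
  vals <- lapply(c(0.9, 0.6, 0.85, 0.7, 0.8, 0.95, 0.75, 0.65), function(v) {
    m <- matrix(0, 3, 3, dimnames = list(panel, panel))
    m["A", "B"] <- m["B", "A"] <- v
    metabnet:::new_correlation_matrix(m, "g", 1, panel)
  })
  bb <- backbone(vals)
  expect_equal(bb$matrix$values["A", "B"], 0.6)
  bb_med <- backbone(vals, aggregate = "median")
  expect_equal(bb_med$matrix$values["A", "B"], median(c(0.9, 0.6, 0.85, 0.7,
                                                        0.8, 0.95, 0.75, 0.65)))
})

test_that("binarized backbone edges are a subset of every time point's edges", {
  set.seed(12)
  panel <- default_panel()
  mats <- lapply(1:8, function(t) {
    vals <- matrix(0, 11, 11)
    vals[upper.tri(vals)] <- runif(55)
    vals <- vals + t(vals)
    dimnames(vals) <- list(panel, panel)
    metabnet:::new_correlation_matrix(vals, "g", t, panel)
  })
  bb <- backbone(mats, alpha = 0.05)
  net_bb <- binarize(bb$matrix, 0.41)
  for (m in mats) {
    expect_true(all(net_bb$adjacency <= binarize(m, 0.41)$adjacency))
  }
})

test_that("strict-mode backbone counts only above-threshold time points", {
  panel <- c("A", "B", "C")
  mk <- function(ab) {
    vals <- matrix(0, 3, 3, dimnames = list(panel, panel))
    vals["A", "B"] <- vals["B", "A"] <- ab
    metabnet:::new_correlation_matrix(vals, "g", 1, panel)
  }
  # |rho| = 0.3 at every time point: nonzero (default mode eligible) but
  # below the 0.41 analysis threshold (strict mode not eligible)
  mats <- rep(list(mk(0.3)), 8)
  expect_true(backbone(mats)$eligible["A", "B"])
  expect_false(backbone(mats, strict_threshold = 0.41)$eligible["A", "B"])
})

test_that("edge lists and matrix CSVs export faithfully", {
  vals <- matrix(0, 3, 3, dimnames = list(c("Cr", "PCr", "Gln"),
                                          c("Cr", "PCr", "Gln")))
  vals["Cr", "PCr"] <- vals["PCr", "Cr"] <- 0.9
  m <- metabnet:::new_correlation_matrix(vals, "g", 1, c("Cr", "PCr", "Gln"))
  net <- binarize(m, 0.41)
  edges <- as_edge_list(net)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$metabolite_a, "Cr")
  expect_equal(edges$metabolite_b, "PCr")
  path <- withr::local_tempfile(fileext = ".tsv")
  as_edge_list(net, path)
  expect_identical(readLines(path)[1], "metabolite_a\tmetabolite_b\tweight")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, csv)
  back <- as.matrix(read.csv(csv, row.names = 1))
  expect_equal(unname(back), unname(vals))
})
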