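test_that("fit_gene_gaussians returns per-gene sample mean and n-1 SD", {
  # degenerate replicates: twelve identical values
  m <- matrix(rep(c(2.5, 7), each = 12), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), NULL))
  g <- fit_gene_gaussians(rm_from_matrix(m, "arch", "Luminal A"))
  expect_equal(g$mu, c(2.5, 7))
  expect_equal(g$sigma, c(0, 0))
  expect_equal(g$n, c(12L, 12L))

  # replicates with exact sample moments, as for the ACTR3B reference values
  v <- replicates_with_moments(12, 1.94, 0.085, seed = 4)
  g2 <- fit_gene_gaussians(rm_from_matrix(matrix(v, nrow = 1,
                                                 dimnames = list("ACTR3B", NULL)),
                                          "archLumB", "Luminal B"))
  expect_equal(g2$mu, 1.94, tolerance = 1e-12)
  expect_equal(g2$sigma, 0.085, tolerance = 1e-12)
  expect_identical(g2$subtype, "Luminal B")
})

test_that("fit_gene_gaussians recovers known parameters from large samples", {
  set.seed(99)
  mu_true <- c(1.94, 6.2); sd_true <- c(0.085, 0.4)
  n <- 10000
  m <- rbind(rnorm(n, mu_true[1], sd_true[1]),
             rnorm(n, mu_true[2], sd_true[2]))
  rownames(m) <- c("gA", "gB")
  g <- fit_gene_gaussians(rm_from_matrix(m, "arch", "Basal-like"))
  expect_equal(g$mu, mu_true, tolerance = 3 * max(sd_true) / sqrt(n))
  expect_true(all(abs(g$sigma / sd_true - 1) < 0.05))
})

test_that("median-centered pooling conserves counts and centers each archetype", {
  genes <- paste0("g", 1:3)
  reps <- c(12, 12, 12, 11)
  rms <- lapply(seq_along(reps), function(i) {
    set.seed(i)
    m <- matrix(rnorm(3 * reps[i], mean = i), nrow = 3,
                dimnames = list(genes, NULL))
    rm_from_matrix(m, paste0("arch", i), c("Luminal A", "Luminal B",
                                           "HER2-enriched", "Basal-like")[i])
  })
  pooled <- pool_median_centered(rms)
  # 12 + 12 + 12 + 11 replicates pooled -> 47 points per gene
  per_gene <- dplyr::count(pooled, gene_id)
  expect_true(all(per_gene$n == 47L))
  # per-archetype, per-gene centered medians are exactly zero
  med <- pooled |>
    dplyr::group_by(gene_id, archetype_id) |>
    dplyr::summarise(m = median(value), .groups = "drop")
  expect_lt(max(abs(med$m)), 1e-12)
})

test_that("pooling a single archetype centers its medians at zero", {
  set.seed(12)
  m <- matrix(rnorm(5 * 9, 3), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  pooled <- pool_median_centered(list(rm_from_matrix(m, "solo", "Luminal A")))
  expect_equal(nrow(pooled), 45L)
  med <- tapply(pooled$value, pooled$gene_id, median)
  expect_lt(max(abs(med)), 1e-12)
})

test_that("pooling rejects mismatched gene sets", {
  m1 <- matrix(rnorm(9), 3, dimnames = list(paste0("g", 1:3), NULL))
  m2 <- matrix(rnorm(9), 3, dimnames = list(paste0("h", 1:3), NULL))
  expect_error(pool_median_centered(list(rm_from_matrix(m1, "a", "X"),
                                         rm_from_matrix(m2, "b", "Y"))),
               "different gene set")
})

test_that("normality diagnostics flag skew and reject degenerate input", {
  set.seed(21)
  gauss <- tibble::tibble(gene_id = "g", value = rnorm(1000))
  d <- normality_summary(gauss)
  expect_lt(abs(d$skewness), 0.2)
  expect_gt(d$shapiro_p, 1e-4)

  skewed <- tibble::tibble(gene_id = "g", value = rexp(1000))
  expect_gt(normality_summary(skewed)$skewness, 1)

  expect_error(normality_summary(tibble::tibble(gene_id = "g",
                                                value = rep(1, 50))),
               "degenerate")
  expect_error(normality_summary(tibble::tibble(gene_id = "g",
                                                value = rnorm(5))),
               ">= 8 points")
})

make_sigma_points <- function(f, n = 50, subtype = "S", seed = 1,
                              noise = 0.002, emin = 1, emax = 9) {
  set.seed(seed)
  e <- runif(n, emin, emax)
  tibble::tibble(expression = e,
                 sigma = pmax(f(e) + rnorm(n, sd = noise), 1e-4),
                 subtype = subtype)
}

test_that("sigma model recovers a known affine sigma(e) within 5%", {
  f <- function(e) 0.05 + 0.01 * e
  pts <- make_sigma_points(f, seed = 31)
  model <- fit_sigma_model(pts, n_boot = 50, seed = 2)
  q <- seq(min(pts$expression), max(pts$expression), length.out = 50)
  pred <- predict_sigma(model, q, "S", "average")
  expect_true(all(abs(pred / f(q) - 1) < 0.05))
})

test_that("sigma model recovers a constant sigma within 2%", {
  pts <- make_sigma_points(function(e) rep(0.2, length(e)), seed = 33,
                           noise = 0.001)
  model <- fit_sigma_model(pts, n_boot = 50, seed = 2)
  q <- seq(1, 9, length.out = 60)
  pred <- predict_sigma(model, q, "S", "average")
  expect_true(all(abs(pred - 0.2) / 0.2 < 0.02))
})

test_that("scenario bands are ordered best <= average <= worst everywhere", {
  pts <- dplyr::bind_rows(
    make_sigma_points(function(e) 0.05 + 0.01 * e, subtype = "S1", seed = 41,
                      noise = 0.01),
    make_sigma_points(function(e) 0.3 - 0.02 * e, subtype = "S2", seed = 42,
                      noise = 0.01))
  model <- fit_sigma_model(pts, n_boot = 50, seed = 3)
  for (s in c("S1", "S2")) {
    q <- seq(0, 11, length.out = 100)  # includes extrapolation territory
    lo <- predict_sigma(model, q, s, "best")
    mid <- predict_sigma(model, q, s, "average")
    hi <- predict_sigma(model, q, s, "worst")
    expect_true(all(lo <= mid + 1e-12))
    expect_true(all(mid <= hi + 1e-12))
    expect_true(all(lo >= model$params$sigma_floor))
  }
  g <- tidy(model)
  expect_true(all(g$lower <= g$fit & g$fit <= g$upper))
})

test_that("predicted sigma is clipped at the configured floor", {
  # decreasing sigma extrapolates negative far beyond the training range
  pts <- make_sigma_points(function(e) 0.3 - 0.03 * e, seed = 51,
                           noise = 0.001)
  model <- fit_sigma_model(pts, n_boot = 20, seed = 4, sigma_floor = 1e-6)
  expect_equal(predict_sigma(model, 50, "S", "average"), 1e-6)
})

test_that("unknown subtypes error unless the pooled fallback is requested", {
  pts <- make_sigma_points(function(e) 0.1 + 0.005 * e, seed = 61)
  model <- fit_sigma_model(pts, n_boot = 20, seed = 5)
  expect_error(predict_sigma(model, 5, "Normal-like", "average"),
               "Normal-like")
  expect_warning(out <- predict_sigma(model, 5, "Normal-like", "average",
                                      fallback = TRUE),
                 "pooled")
  expect_true(is.finite(out) && out > 0)
})

test_that("a subtype with too few points is rejected by name", {
  pts <- dplyr::bind_rows(make_sigma_points(function(e) 0.1 + 0 * e, n = 30,
                                            subtype = "Plenty", seed = 71),
                          make_sigma_points(function(e) 0.1 + 0 * e, n = 5,
                                            subtype = "Sparse", seed = 72))
  expect_error(fit_sigma_model(pts), "Sparse")
})

test_that("sigma model JSON round trip reproduces predictions exactly", {
  pts <- make_sigma_points(function(e) 0.05 + 0.01 * e, seed = 81)
  model <- fit_sigma_model(pts, n_boot = 20, seed = 6)
  tf <- withr::local_tempfile(fileext = ".json")
  write_sigma_model_json(model, tf)
  back <- read_sigma_model_json(tf)
  q <- seq(1, 9, length.out = 25)
  for (sc in c("best", "average", "worst")) {
    expect_equal(predict_sigma(back, q, "S", sc),
                 predict_sigma(model, q, "S", sc), tolerance = 1e-9)
  }
})
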