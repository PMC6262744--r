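test_that("stand variables match hand-computed values", {
  # 60 trees of 20 cm on a 500 m2 plot (EF = 20)
  tl <- data.frame(plot_id = "p1", occasion = 0L, d_cm = rep(20, 60),
                   species = "NOB", ef = 20)
  sv <- compute_stand_variables(tl)
  expect_equal(sv$n_ha, 1200)
  expect_equal(sv$dg_cm, 20)
  expect_equal(sv$g_m2ha, 60 * 20 * (pi / 40000) * 400)
  expect_equal(sv$pba_pct, 100)

  # single-tree identity
  one <- data.frame(plot_id = "p1", occasion = 0L, d_cm = 25.4,
                    species = "LAU", ef = 1)
  sv1 <- compute_stand_variables(one)
  expect_equal(sv1$n_ha, 1)
  expect_equal(sv1$dg_cm, 25.4)
  expect_equal(sv1$pba_pct, 0)

  # quadratic-mean definition
  two <- data.frame(plot_id = "p1", occasion = 0L, d_cm = c(10, 20),
                    species = c("NOB", "LAU"), ef = 1)
  expect_equal(compute_stand_variables(two)$dg_cm, sqrt(250))
})

test_that("stand variable preconditions are enforced", {
  expect_error(compute_stand_variables(NULL), "no trees")
  bad <- data.frame(plot_id = "p1", occasion = 0L, d_cm = c(10, -1),
                    species = "NOB", ef = 1)
  expect_error(compute_stand_variables(bad), "diameter")
  mixed <- data.frame(plot_id = c("p1", "p2"), occasion = 0L, d_cm = 10,
                      species = "NOB", ef = 1)
  expect_error(compute_stand_variables(mixed), "single plot-occasion")
})

test_that("G equals (pi/40000) dg^2 N for any tree list", {
  set.seed(42)
  for (r in 1:20) {
    m <- sample(5:80, 1)
    tl <- data.frame(plot_id = "p", occasion = 0L,
                     d_cm = runif(m, 5, 60),
                     species = sample(c("NOB", "LAU"), m, TRUE),
                     ef = runif(m, 1, 25))
    sv <- compute_stand_variables(tl)
    expect_equal(sv$g_m2ha, (pi / 40000) * sv$dg_cm^2 * sv$n_ha,
                 tolerance = 1e-12)
    expect_gte(sv$pba_pct, 0)
    expect_lte(sv$pba_pct, 100)
  }
})

test_that("Shannon index matches closed forms and is scale invariant", {
  expect_equal(shannon_index(5), 0)
  expect_equal(shannon_index(c(1, 1)), log(2))
  p <- c(.4, .3, .2, .1)
  expect_equal(shannon_index(p), -sum(p * log(p)))
  expect_equal(shannon_index(p * 1000), shannon_index(p))
  # maximized at equal proportions
  set.seed(1)
  for (r in 1:10) {
    q <- rgamma(4, 1); q <- q / sum(q)
    expect_lte(shannon_index(q), shannon_index(rep(1, 4)) + 1e-12)
  }
  expect_error(shannon_index(c(0, 0)), "zero")
})

test_that("shannon is bounded by ln richness in site covariates", {
  set.seed(3)
  tl <- data.frame(plot_id = "p", occasion = 0L, d_cm = runif(30, 5, 40),
                   species = sample(c("NOB", "NAL", "LAU"), 30, TRUE),
                   ef = 10)
  sc <- site_covariates(tl)
  expect_lte(sc$shannon, log(sc$richness))
  expect_gte(sc$d_cv, 0)
})

test_that("diameter statistics handle weights and degenerate lists", {
  eq <- data.frame(d_cm = rep(15, 5), ef = rep(2, 5))
  s <- diameter_distribution_stats(eq)
  expect_equal(s$d_sd, 0)
  expect_equal(s$d_cv, 0)
  expect_equal(s$d_skew, 0)

  three <- data.frame(d_cm = c(10, 20, 30), ef = rep(1, 3))
  s3 <- diameter_distribution_stats(three)
  expect_equal(s3$d_median, 20)
  expect_equal(s3$d_sd, sqrt(mean((c(10, 20, 30) - 20)^2)))
  expect_equal(s3$d_skew, 0)   # symmetric

  one <- data.frame(d_cm = 10, ef = 1)
  s1 <- diameter_distribution_stats(one)
  expect_true(is.na(s1$d_sd))
  expect_true(is.na(s1$d_skew))

  # expansion factors act as frequency weights: duplicating a tree via ef
  # equals listing it twice
  a <- data.frame(d_cm = c(10, 20, 30), ef = c(2, 1, 1))
  b <- data.frame(d_cm = c(10, 10, 20, 30), ef = rep(1, 4))
  expect_equal(diameter_distribution_stats(a), diameter_distribution_stats(b))
})

test_that("plot table validation flags inconsistent rows", {
  pl <- data.frame(plot_id = c("a", "a", "b"), occasion = c(0, 1, 0),
                   n_ha = c(1000, 900, -5), dg_cm = c(20, 25, 15))
  v <- validate_plot_table(pl)
  expect_match(attr(v, "issues"), "non-positive", all = FALSE)

  pl2 <- data.frame(plot_id = c("a", "a"), occasion = c(0, 1),
                    n_ha = c(1000, 900), dg_cm = c(25, 20))
  expect_match(attr(validate_plot_table(pl2), "issues"), "dg decreases",
               all = FALSE)
  expect_error(validate_plot_table(data.frame(plot_id = "a")), "missing")
})
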