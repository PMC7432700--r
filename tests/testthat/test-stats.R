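# Subject-level aggregation and the Kruskal-Wallis / post-hoc U workflow.

test_that("two-level aggregation averages subjects, not observations", {
  df <- tibble::tibble(subject_id = c("A", "A", "B"), v = c(10, 20, 30))
  agg <- aggregate_subjects(df, v)
  expect_equal(sort(agg$per_subject$mean), c(15, 30))
  expect_equal(agg$overall$mean, 22.5)
  expect_identical(agg$overall$n_subjects, 2L)
  expect_equal(glance(agg)$mean, 22.5)
  expect_identical(nrow(tidy(agg)), 2L)
})

test_that("a single subject yields its mean and an undefined SD", {
  df <- tibble::tibble(subject_id = "A", v = c(1, 2, 3))
  agg <- aggregate_subjects(df, v)
  expect_equal(agg$overall$mean, 2)
  expect_true(is.na(agg$overall$sd))
})

test_that("subjects without observations are excluded with a warning", {
  df <- tibble::tibble(subject_id = c("A", "A", "B"), v = c(1, 2, NA))
  expect_warning(agg <- aggregate_subjects(df, v), "excluded")
  expect_identical(agg$overall$n_subjects, 1L)
})

test_that("subject-level grand means recover the generator's configured mean", {
  # 5 subjects x 25 synapses: cleft laterals drawn around a known value
  set.seed(77)
  mu <- 17.24
  recs <- list()
  for (s in 1:5) {
    subj_mu <- mu + rnorm(1, 0, 0.4)
    for (i in 1:25) {
      l1 <- subj_mu + rnorm(1, 0, 1.5); l2 <- subj_mu + rnorm(1, 0, 1.5)
      recs[[length(recs) + 1L]] <-
        measure_cleft(l1, l2, subj_mu + 2, subject_id = paste0("s", s))
    }
  }
  df <- dplyr::bind_rows(recs)
  agg <- aggregate_subjects(df, lateral_mean)
  expect_equal(agg$overall$mean, mu, tolerance = 0.05)
})

test_that("the omnibus H statistic matches hand-computed rank arithmetic", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_posthoc(groups)
  # hand computation: ranks 1..9, rank sums 6, 15, 24, no ties
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  H_hand <- 12 / (9 * 10) * (36 / 3 + 225 / 3 + 576 / 3) - 3 * 10
  expect_equal(res$H, H_hand)
  expect_identical(nrow(res$pairwise), 3L)
})

test_that("identical groups give a near-zero H and large p", {
  g <- list(a = 1:10, b = 1:10, c = 1:10)
  res <- kruskal_posthoc(g)
  expect_lt(res$H, 1e-9)
  expect_gt(res$p_value, 0.99)
})

test_that("groups with fewer than two values are rejected by name", {
  expect_error(kruskal_posthoc(list(a = 1:5, tiny = 3)), "tiny")
  expect_error(kruskal_posthoc(list(a = 1:5)), "2 groups")
})

test_that("data-frame interface and broom methods work together", {
  df <- tibble::tibble(v = c(rnorm(10), rnorm(10, 2)),
                       g = rep(c("x", "y"), each = 10L))
  res <- kruskal_posthoc(df, v, g)
  expect_s3_class(res, "syn_kruskal")
  td <- tidy(res)
  expect_identical(names(td), c("group1", "group2", "U", "p_value", "p_adjusted"))
  gl <- glance(res)
  expect_identical(gl$n_groups, 2L)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
  expect_true(all(td$p_adjusted >= td$p_value))
})

test_that("type-I error is calibrated across group sizes", {
  set.seed(2024)
  for (n in c(5, 20)) {
    rej <- mean(vapply(1:800, function(i) {
      g <- list(a = rnorm(n), b = rnorm(n), c = rnorm(n))
      stats::kruskal.test(g)$p.value < 0.05
    }, TRUE))
    expect_gt(rej, 0.03)
    expect_lt(rej, 0.07)
  }
})
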