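test_that("group summaries: Grubbs first, then mean and SEM", {
  s <- summarize_group(c(2, 4, 6))
  expect_equal(s$mean_s, 4)
  expect_equal(s$sem_s, 2 / sqrt(3))
  expect_equal(s$n_before, 3)

  s <- summarize_group(c(5.1, 5.3, 5.0, 5.2, 9.8))
  expect_equal(s$n_after, 4)
  expect_equal(s$mean_s, mean(c(5.1, 5.3, 5.0, 5.2)))
  expect_equal(s$removed[[1]], 9.8)

  s <- summarize_group(7.5)
  expect_equal(s$mean_s, 7.5)
  expect_true(is.na(s$sem_s))
})

test_that("summarize_groups warns below ten cells per group", {
  df <- tibble::tibble(group = rep(c("a", "b"), c(12, 5)),
                       t_half_s = c(rnorm(12, 6), rnorm(5, 3)))
  expect_warning(summarize_groups(df), class = "frapkin_warning_small_group")
})

test_that("Tukey-Kramer adjusted p-values match TukeyHSD on random designs", {
  set.seed(55)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    df <- purrr::map(seq_len(k), function(g) {
      n <- sample(4:12, 1)
      tibble::tibble(group = paste0("g", g),
                     t_half_s = rnorm(n, mean = 5 + g * runif(1), sd = 1))
    }) |> purrr::list_rbind()
    ours <- anova_tukey(df)
    ref <- stats::TukeyHSD(stats::aov(t_half_s ~ group, data = df))$group
    key <- paste0(ours$pairs$group_b, "-", ours$pairs$group_a)
    key2 <- paste0(ours$pairs$group_a, "-", ours$pairs$group_b)
    for (j in seq_len(nrow(ours$pairs))) {
      row <- if (key[j] %in% rownames(ref)) key[j] else key2[j]
      expect_equal(ours$pairs$p_adj[j], ref[row, "p adj"], tolerance = 1e-6)
    }
    # overall F matches the classical ANOVA table
    tab <- summary(stats::aov(t_half_s ~ group, data = df))[[1]]
    expect_equal(ours$f, tab[["F value"]][1], tolerance = 1e-9)
    expect_equal(ours$p_value, tab[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("two-group Tukey reduces to the pooled t test (q^2 = 2 t^2)", {
  set.seed(66)
  df <- tibble::tibble(group = rep(c("a", "b"), c(9, 13)),
                       t_half_s = c(rnorm(9, 6, 1), rnorm(13, 7, 1)))
  ours <- anova_tukey(df)
  tt <- stats::t.test(t_half_s ~ group, data = df, var.equal = TRUE)
  expect_equal(ours$pairs$q[1]^2, 2 * unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(ours$pairs$p_adj[1], tt$p.value, tolerance = 1e-6)
})

test_that("identical groups are never significant; MSE = 0 is flagged", {
  df <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                       t_half_s = rep(4.2, 10))
  cmp <- anova_tukey(df)
  expect_false(any(cmp$pairs$significant))
  expect_true(cmp$degenerate)

  df2 <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                        t_half_s = rep(c(4.2, 9.9), each = 5))
  cmp2 <- anova_tukey(df2)
  expect_true(cmp2$degenerate)
  expect_true(all(cmp2$pairs$significant))
  expect_equal(cmp2$pairs$p_adj, 0)

  expect_error(anova_tukey(df[df$group == "a", ]),
               class = "frapkin_error_stats")
})

test_that("selectivity profile: control at 100%, simple arithmetic, scaling invariance", {
  # outlier-free values with exact means 6 and 3 so the percentage is exact
  spread <- seq(-0.11, 0.11, length.out = 12)
  df <- tibble::tibble(
    group = rep(c("ctrl", "treated"), each = 12),
    t_half_s = c(6 + spread, 3 + spread))

  prof <- selectivity_profile(df, "ctrl")
  ctrl_row <- prof[prof$group == "ctrl", ]
  expect_equal(ctrl_row$percent_of_control, 100)
  expect_false(ctrl_row$significant_vs_control)
  expect_equal(prof$percent_of_control[prof$group == "treated"], 50,
               tolerance = 1e-9)
  expect_true(prof$significant_vs_control[prof$group == "treated"])

  # invariant to a common rescaling of all half times
  prof2 <- selectivity_profile(dplyr::mutate(df, t_half_s = t_half_s * 3.5),
                               "ctrl")
  expect_equal(prof2$percent_of_control, prof$percent_of_control,
               tolerance = 1e-9)
  expect_equal(prof2$sem_percent, prof$sem_percent, tolerance = 1e-9)

  expect_error(selectivity_profile(df, "missing"),
               class = "frapkin_error_stats")
})

test_that("a selective inhibitor flags only its true targets", {
  # ten targets, each with its own control; the inhibitor halves the true
  # t-half of targets 3 and 7 only
  hit <- c(3, 7)
  sens <- matrix(NA, nrow = 20, ncol = 10)
  seed0 <- 900
  for (r in 1:20) {
    set.seed(seed0 + r)
    for (tg in 1:10) {
      base <- 2 + tg
      eff <- if (tg %in% hit) 0.5 else 1
      df <- tibble::tibble(
        group = rep(c("ctrl", "inh"), each = 10),
        t_half_s = c(rlnorm(10, log(base), 0.15),
                     rlnorm(10, log(base * eff), 0.15)))
      prof <- suppressWarnings(selectivity_profile(df, "ctrl"))
      sens[r, tg] <- prof$significant_vs_control[prof$group == "inh"]
    }
  }
  hit_rate <- colMeans(sens)[hit]
  null_rate <- mean(sens[, -hit])
  expect_true(all(hit_rate >= 0.95))
  expect_lte(null_rate, 0.05 + 2 * sqrt(0.05 * 0.95 / (20 * 8)))
})
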