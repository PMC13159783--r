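test_that("ASQ domain scoring follows the point scale and thresholds", {
  rec <- make_asq_record()
  sc <- score_asq(rec)
  expect_equal(sc$communication_score, 60)
  expect_equal(sc$asq_total_score, 300)
  expect_false(sc$asq_total_abnormal)
  expect_true(sc$asq_analyzable)

  # communication 30 -> abnormal (threshold 35); personal-social 30 ->
  # normal (threshold 25)
  rec2 <- make_asq_record(list(communication = items_for_score(30),
                               personal_social = items_for_score(30)))
  sc2 <- score_asq(rec2)
  expect_true(sc2$communication_abnormal)
  expect_false(sc2$personal_social_abnormal)

  expect_error(score_asq(make_asq_record(list(
    communication = c("yes", "often", "yes", "yes", "yes", "yes")))),
    "invalid ASQ response")
})

test_that("missing-item adjustment matches the mean-of-answered rule", {
  # five answered items summing 40, one missing -> 40/5*6 = 48
  toks <- c("yes", "yes", "yes", "yes", "not_yet", "missing")
  sc <- score_asq(make_asq_record(list(gross_motor = toks)))
  expect_equal(sc$gross_motor_score, 48)

  # adjusted equals raw when nothing is missing
  full <- items_for_score(40)
  expect_equal(score_asq(make_asq_record(list(gross_motor = full)))$
                 gross_motor_score, 40)

  # three missing items -> domain undefined, total undefined
  toks3 <- c("yes", "yes", "yes", NA, NA, NA)
  sc3 <- score_asq(make_asq_record(list(fine_motor = toks3)))
  expect_true(is.na(sc3$fine_motor_score))
  expect_true(is.na(sc3$asq_total_score))
})

test_that("total-score threshold and age window classify correctly", {
  # five domains at 44 -> total 220 -> abnormal; 45 each -> 225 -> normal
  # (44 is not reachable from 5-point items, so use 40+48 mix: instead
  # construct 220 as 60+60+40+35+25)
  scores <- c(communication = 60, gross_motor = 60, fine_motor = 40,
              problem_solving = 35, personal_social = 25)
  rec <- make_asq_record(lapply(as.list(scores), items_for_score))
  sc <- score_asq(rec)
  expect_equal(sc$asq_total_score, 220)
  expect_true(sc$asq_total_abnormal)

  scores["personal_social"] <- 30
  sc2 <- score_asq(make_asq_record(lapply(as.list(scores),
                                          items_for_score)))
  expect_equal(sc2$asq_total_score, 225)
  expect_false(sc2$asq_total_abnormal)

  late <- score_asq(make_asq_record(age_months = 27))
  expect_false(late$asq_analyzable)
  edge <- score_asq(make_asq_record(age_months = 21))
  expect_true(edge$asq_analyzable)
})

test_that("upgrading any item response never worsens a domain", {
  set.seed(3)
  upgrade <- c(not_yet = "sometimes", sometimes = "yes", yes = "yes")
  for (i in 1:20) {
    toks <- sample(c("yes", "sometimes", "not_yet"), 6, replace = TRUE)
    sc <- score_asq(make_asq_record(list(problem_solving = toks)))
    j <- sample(6, 1)
    toks2 <- toks
    toks2[j] <- upgrade[[toks[j]]]
    sc2 <- score_asq(make_asq_record(list(problem_solving = toks2)))
    expect_gte(sc2$problem_solving_score, sc$problem_solving_score)
    expect_true(!(sc2$problem_solving_abnormal &&
                    !sc$problem_solving_abnormal))
  }
})

test_that("group comparisons dispatch the right test and match enumeration", {
  co <- data.frame(grp = rep(c("x", "y"), each = 3),
                   delta34_weeks = c(1, 2, 3, 11, 12, 13))
  row <- compare_delta_by_factor(co, "grp")
  expect_equal(unique(row$test), "Mann-Whitney-Wilcoxon")
  expect_equal(row$median, c(2, 12))
  expect_equal(unique(row$p_value),
               oracle_rank_perm_p(c(1, 2, 3), c(11, 12, 13)))

  same <- data.frame(grp = rep(c("x", "y"), each = 3),
                     delta34_weeks = rep(c(1, 2, 3), 2))
  expect_gte(unique(compare_delta_by_factor(same, "grp")$p_value), 0.99)

  three <- data.frame(grp = rep(c("x", "y", "z"), each = 4),
                      delta34_weeks = rnorm(12))
  expect_equal(unique(compare_delta_by_factor(three, "grp")$test),
               "Kruskal-Wallis")
  expect_equal(unique(compare_delta_by_factor(three, "grp",
                                              parametric = TRUE)$test),
               "ANOVA")
})

test_that("categorical association dispatches on expected counts", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- categorical_assoc(even)
  expect_equal(res$test, "chi-square")
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  sparse <- matrix(c(2, 4, 4, 77), 2, byrow = TRUE)
  expect_equal(categorical_assoc(sparse)$test, "fisher")
  expect_true(any(categorical_assoc(sparse)$expected < 5))

  big <- matrix(c(20, 30, 25, 35, 30, 40), 3, byrow = TRUE)
  expect_equal(categorical_assoc(big)$test, "chi-square")
  expect_error(categorical_assoc(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  co <- data.frame(
    exposed = c(rep(1, 6), rep(0, 81)),
    event = c(rep(1, 2), rep(0, 4), rep(1, 4), rep(0, 77)))
  res <- logistic_or(co, "event", "exposed")
  expect_equal(res$or, (2 / 4) / (4 / 77), tolerance = 1e-3)
  expect_false(res$separation)
  expect_true(res$ci_low < res$or && res$or < res$ci_high)
})

test_that("logistic OR is consistent under the null and flags separation", {
  set.seed(8)
  co <- data.frame(x = rnorm(20000), y = rbinom(20000, 1, 0.3))
  expect_lt(abs(logistic_or(co, "y", "x")$or - 1), 0.1)

  sep <- data.frame(x = c(1:10, 21:30), y = rep(c(0, 1), each = 10))
  res <- logistic_or(sep, "y", "x")
  expect_true(res$separation)
  expect_equal(res$or, Inf)

  allz <- data.frame(x = rnorm(50), y = 0)
  expect_error(logistic_or(allz, "y", "x"), "both classes")
})

test_that("the descriptive table reports N (%) as printed", {
  co <- generate_cohort(cohort_gen_config(n_infants = 132, seed = 21))
  co$delta34_weeks <- co$delta34_true
  tab <- build_table1(co)
  sex_rows <- tab[tab$variable == "sex", ]
  expect_equal(sum(sex_rows$n), 132)
  expect_equal(sex_rows$percent,
               round(100 * sex_rows$n / 132, 1))
  # percents within a variable sum to 100 up to rounding
  for (v in unique(tab$variable)) {
    expect_lt(abs(sum(tab$percent[tab$variable == v]) - 100), 0.21)
  }
  expect_warning(build_table1(co, variables = c("sex", "nonexistent")),
                 "omitted")
  # a cohort of 132 with a 68-member category prints 51.5
  co2 <- data.frame(f = rep(c("m", "f"), c(68, 64)),
                    delta34_weeks = rnorm(132))
  t2 <- compare_delta_by_factor(co2, "f")
  expect_equal(t2$percent[t2$category == "m"], 51.5)
})

test_that("cohort flow arithmetic matches the study design", {
  flow <- cohort_flow(170, 23, 15, 87)
  expect_equal(flow$n_included, 132)
  expect_equal(flow$included_percent, 78)  # 132/170 = 77.6, rounded
  expect_equal(flow$followup_percent, 66)
  expect_error(cohort_flow(30, 20, 15), "exceed")
})
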