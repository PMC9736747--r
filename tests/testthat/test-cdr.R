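test_that("connection counts tally distinct patients per cohort", {
  g <- toy_count_graph(12, 0)
  cc <- count_connections(g)
  expect_equal(cc$tpc, 12L)
  expect_equal(cc$bpc, 0L)

  expect_error(count_connections(g, factors = "Condition|C-nope|true"),
               class = "cdrgraph_not_found_error")
})

test_that("a duplicated observation still counts a patient once", {
  pts <- tibble::tibble(virtual_id = c("_1", "_2"), label = c(1L, 0L))
  obs <- tibble::tibble(
    virtual_id = c("_1", "_1", "_2"), category = "Labtest", code = "C-1",
    term = "T", value = "up", unit = "", converted_value = "up",
    date = as.Date("2021-01-01")
  )
  cc <- count_connections(build_patient_graph(pts, obs))
  expect_equal(cc$tpc, 1L)
  expect_equal(cc$bpc, 1L)
})

test_that("the connection delta ratio evaluates exactly", {
  expect_equal(cdr(12, 0), 1)
  expect_equal(cdr(7, 7), 0)
  expect_equal(cdr(30, 10), 0.5)
  expect_equal(cdr(19, 1), 0.9)
  expect_equal(cdr(18, 2), 0.8)
  expect_equal(cdr(0, 5), -1)
  expect_error(cdr(0, 0), class = "cdrgraph_config_error")
  expect_error(cdr(-1, 2), class = "cdrgraph_config_error")
})

test_that("CDR is antisymmetric, bounded, and monotone in its counts", {
  withr::with_seed(17, {
    t <- sample(0:50, 200, replace = TRUE)
    b <- sample(0:50, 200, replace = TRUE)
  })
  keep <- t + b >= 1
  t <- t[keep]; b <- b[keep]
  expect_equal(cdr(t, b), -cdr(b, t))
  expect_true(all(abs(cdr(t, b)) <= 1))
  at_bound <- abs(cdr(t, b)) == 1
  expect_equal(at_bound, t == 0 | b == 0)
  # strictly increasing in tpc (constant at the bpc = 0 boundary, where
  # CDR is pinned at 1), strictly decreasing in bpc (likewise at tpc = 0)
  expect_true(all(cdr(t + 1, b)[b > 0] > cdr(t, b)[b > 0]))
  expect_true(all(cdr(t + 1, b)[b == 0] == 1))
  expect_true(all(cdr(t, b + 1)[t > 0] < cdr(t, b)[t > 0]))
  expect_true(all(cdr(t, b + 1)[t == 0] == -1))
})

test_that("empirical CDR recovers the analytic attachment contrast", {
  grid <- tidyr::expand_grid(p_t = seq(0, 0.9, by = 0.1), p_b = c(0.4, 0.8))
  specs <- dplyr::mutate(
    grid,
    category = "Observation", code = sprintf("C-%03d", dplyr::row_number()),
    term = code, converted_value = "true"
  )
  coh <- generate_cohort(cohort_config(specs, 1000, 1000, seed = 42))
  g <- build_patient_graph(coh$patients, coh$factors)
  est <- dplyr::left_join(tidy(g), specs, by = "code")
  expect_equal(nrow(est), 20)
  expected <- (est$p_t - est$p_b) / (est$p_t + est$p_b)
  expect_true(all(abs(est$cdr - expected) < 0.05))
})

test_that("swapping cohort labels negates every CDR and reverses the order", {
  withr::with_seed(29, fx <- random_graph_fixture(n_patients = 50))
  g <- fx$graph
  swapped <- build_patient_graph(
    dplyr::mutate(fx$patients, label = 1L - label),
    fx$observations
  )
  a <- dplyr::arrange(tidy(g), factor_id)
  b <- dplyr::arrange(tidy(swapped), factor_id)
  expect_equal(b$cdr, -a$cdr)
  cfg <- distribution_config(cdr_cutoff = -0.99, min_target_connections = 0,
                             excluded_categories = character(),
                             excluded_patterns = character())
  da <- suppressWarnings(build_distribution(g, cfg))
  db <- suppressWarnings(build_distribution(swapped, cfg))
  ka <- paste(da$category, da$code, da$converted_value)
  kb <- paste(db$category, db$code, db$converted_value)
  common <- intersect(ka, kb)
  ca <- da$cdr[match(common, ka)]
  cb <- db$cdr[match(common, kb)]
  expect_equal(ca, -cb)
  # CDR ranking reverses under the label swap (average ranks to absorb ties)
  expect_equal(rank(ca), length(ca) + 1 - rank(cb))
})

test_that("the distribution applies strict cutoff, support, and sort contracts", {
  pts <- tibble::tibble(
    virtual_id = sprintf("_%03d", 1:120),
    label = rep(c(1L, 0L), each = 60)
  )
  mk <- function(code, n_t, n_b, category = "Condition") {
    tibble::tibble(
      virtual_id = c(pts$virtual_id[seq_len(n_t)],
                     pts$virtual_id[60 + seq_len(n_b)]),
      category = category, code = code, term = paste("Term", code),
      value = "true", unit = "", converted_value = "true",
      date = as.Date("2021-01-01")
    )
  }
  obs <- dplyr::bind_rows(
    mk("C-A", 30, 10),  # cdr exactly 0.50 -> excluded by strict cutoff
    mk("C-B", 19, 1),   # 0.90 kept
    mk("C-C", 18, 2),   # 0.80 kept
    mk("C-D", 9, 0),    # cdr 1 but tpc 9 -> support-excluded
    mk("C-E", 24, 4)    # 0.714 kept
  )
  g <- build_patient_graph(pts, obs)
  d <- build_distribution(g, distribution_config())
  expect_equal(d$code, c("C-B", "C-C", "C-E"))
  expect_equal(d$cdr, c(0.9, 0.8, 0.7142857), tolerance = 1e-6)
  expect_equal(d$rank, 1:3)
})

test_that("equal CDRs break ties by larger TPC then code", {
  pts <- tibble::tibble(
    virtual_id = sprintf("_%03d", 1:200),
    label = rep(c(1L, 0L), each = 100)
  )
  mk <- function(code, n_t, n_b) {
    tibble::tibble(
      virtual_id = c(pts$virtual_id[seq_len(n_t)],
                     pts$virtual_id[100 + seq_len(n_b)]),
      category = "Symptom", code = code, term = code, value = "true",
      unit = "", converted_value = "true", date = as.Date("2021-01-01")
    )
  }
  obs <- dplyr::bind_rows(
    mk("C-Z", 18, 2), # 0.8, tpc 18
    mk("C-M", 36, 4), # 0.8, tpc 36
    mk("C-A", 18, 2)  # 0.8, tpc 18
  )
  d <- build_distribution(build_patient_graph(pts, obs))
  expect_equal(d$code, c("C-M", "C-A", "C-Z"))
})

test_that("category and term exclusions remove care-of-disease factors", {
  pts <- tibble::tibble(
    virtual_id = sprintf("_%03d", 1:40),
    label = rep(c(1L, 0L), each = 20)
  )
  mk <- function(code, term, category) {
    tibble::tibble(
      virtual_id = pts$virtual_id[1:15], category = category, code = code,
      term = term, value = "true", unit = "", converted_value = "true",
      date = as.Date("2021-01-01")
    )
  }
  obs <- dplyr::bind_rows(
    mk("C-1", "Chemotherapy", "Procedure"),
    mk("C-2", "Lung cancer of left lobe", "Condition"),
    mk("C-3", "Pneumothorax", "Condition")
  )
  g <- build_patient_graph(pts, obs)
  d <- suppressWarnings(build_distribution(g, distribution_config()))
  expect_equal(d$code, "C-3")
})

test_that("zero surviving entries and bias flags are reported, not errors", {
  g <- toy_count_graph(5, 5)
  d <- build_distribution(g)
  expect_equal(nrow(d), 0)
  g1 <- toy_count_graph(12, 0, code = "C-659218", term = "Hepatitis B virus")
  expect_warning(build_distribution(g1), regexp = "background")
})

test_that("the exported distribution matches the tabular conventions", {
  g <- toy_count_graph(19, 1, category = "Labtest", code = "C-493765",
                       value = "up", term = "Squamous cell carcinoma antigen")
  d <- build_distribution(g)
  path <- withr::local_tempfile(fileext = ".csv")
  export_distribution(d, path, tags = c("C-493765" = "confirmed"))
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(out), c("Category", "Local code", "Term", "Value",
                             "Connection delta ratio", "Tag"))
  expect_equal(nrow(out), 1)
  expect_equal(out$Category, "lab")
  expect_equal(out$`Connection delta ratio`, 0.90)
  expect_equal(out$Tag, "confirmed")

  empty <- build_distribution(toy_count_graph(5, 5))
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_distribution(empty, p2)
  expect_equal(length(readLines(p2)), 1) # header only
})

test_that("the distribution curve plot builds without error", {
  g <- toy_count_graph(18, 2, category = "Symptom", code = "C-127089",
                       term = "Hoarseness")
  d <- build_distribution(g)
  p <- autoplot(d)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[2]]), 1)
})

test_that("glance summarises graphs and distributions", {
  g <- toy_count_graph(18, 2)
  expect_equal(glance(g)$n_edges, 20)
  d <- build_distribution(g)
  gl <- glance(d)
  expect_equal(gl$n_factors, 1)
  expect_equal(gl$cdr_cutoff, 0.5)
  expect_equal(tidy(d)$cdr, 0.8)
})
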