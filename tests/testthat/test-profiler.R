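test_that("occurrence counting distinguishes article and heading units", {
  res <- tibble::tibble(article_id = c("1", "1", "2"),
                        metaterm = c("cardiology", "genetics", "cardiology"),
                        support = c(3L, 1L, 2L))
  art <- count_occurrences(res, "article")
  expect_equal(art$count[art$metaterm == "cardiology"], 2L)
  hd <- count_occurrences(res, "heading")
  expect_equal(hd$count[hd$metaterm == "cardiology"], 5L)
  expect_equal(nrow(count_occurrences(res[0, ], "article")), 0)

  # one article, support 3: article unit 1, heading unit 3
  one <- res[1, ]
  expect_equal(count_occurrences(one, "article")$count, 1L)
  expect_equal(count_occurrences(one, "heading")$count, 3L)
})

test_that("relative weights are percent shares with a guarded denominator", {
  expect_equal(relative_weight(0, 50), 0)
  expect_equal(relative_weight(25, 100), 25)
  expect_equal(relative_weight(1, 3), 33.33)
  expect_error(relative_weight(1, 0), "total 0")
})

test_that("profile weights sum to 100 and ranking breaks ties alphabetically", {
  cfg <- generator_config(seed = 3, journals = "Lancet", years = 1997L,
                          n_articles_per_cell = 120, n_specialties = 4,
                          branching = 4, tree_depth = 2)
  toy <- generate_toy_thesaurus(cfg)
  corp <- generate_corpus(cfg, toy)
  prof <- journal_year_profile(corp, toy$thesaurus, toy$links, "Lancet")
  expect_equal(sum(prof$table$weight), 100, tolerance = 1e-10)
  expect_equal(prof$total, sum(prof$table$count))

  tied <- prof
  tied$table <- tibble::tibble(metaterm = c("ccc", "aaa", "bbb"),
                               count = c(1L, 5L, 5L),
                               weight = c(1, 5, 5) / 11 * 100)
  rk <- rank_metaterms(tied)
  expect_equal(rk$metaterm, c("aaa", "bbb", "ccc"))
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$weight) <= 0))
  expect_equal(nrow(rank_metaterms(tied, top_n = 2)), 2)

  # rank order equals an independent sort on randomized tables
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    counts <- sample(1:6, n, replace = TRUE)
    p <- prof
    p$table <- tibble::tibble(metaterm = sprintf("m%02d", sample(n)),
                              count = counts,
                              weight = counts / sum(counts) * 100)
    got <- rank_metaterms(p)
    want <- p$table[order(-p$table$weight, p$table$metaterm), ]$metaterm
    expect_equal(got$metaterm, want)
  }
})

test_that("trend percents reproduce printed-style rounding", {
  expect_equal(trend_percent(3.61, 0.88), -76L)
  expect_equal(trend_percent(7.08, 4.87), -31L)
  expect_equal(trend_percent(4.58, 9.47), 107L)
  expect_equal(trend_percent(2, 2), 0L)
  expect_equal(trend_percent(8, 12.21), 53L)  # 52.6% rounds up
  expect_equal(trend_percent(8, 3.8), -53L)   # -52.5% likewise
  expect_error(trend_percent(0, 5), "starting weight")
  # antitone in start, monotone in end
  expect_true(trend_percent(3, 6) > trend_percent(4, 6))
  expect_true(trend_percent(3, 6) < trend_percent(3, 7))
})

test_that("pooling sums counts and is consistent with one-pass profiling", {
  cfg <- generator_config(seed = 5, journals = "BMJ",
                          years = c(1997L, 2002L, 2007L),
                          n_articles_per_cell = 60, n_specialties = 3,
                          branching = 3, tree_depth = 2)
  toy <- generate_toy_thesaurus(cfg)
  corp <- generate_corpus(cfg, toy)
  per_year <- lapply(cfg$years, function(y)
    journal_year_profile(corp, toy$thesaurus, toy$links, "BMJ", years = y))
  pooled <- pooled_profile(per_year)
  direct <- journal_year_profile(corp, toy$thesaurus, toy$links, "BMJ")
  expect_equal(pooled$table, direct$table)
  expect_equal(pooled$total, direct$total)

  # pooling a profile with itself doubles counts, preserves weights
  dbl <- pooled_profile(list(direct, direct))
  expect_equal(dbl$table$count, direct$table$count * 2L)
  expect_equal(dbl$table$weight, direct$table$weight)

  # disjoint single-metaterm profiles of equal totals -> 50/50
  p1 <- direct; p1$table <- tibble::tibble(metaterm = "a", count = 10L,
                                           weight = 100); p1$total <- 10L
  p2 <- direct; p2$table <- tibble::tibble(metaterm = "b", count = 10L,
                                           weight = 100); p2$total <- 10L
  half <- pooled_profile(list(p1, p2))
  expect_equal(half$table$weight, c(50, 50))

  bad <- direct; bad$unit <- "heading"
  expect_error(pooled_profile(list(direct, bad)), "mixed")
  other <- direct; other$journal <- "JAMA"
  expect_error(pooled_profile(list(direct, other)), "cross_journal")
  expect_equal(pooled_profile(list(direct, other),
                              cross_journal = TRUE)$journal, "all")
})

test_that("top-N overlap is the exact intersection of top lists", {
  mk <- function(metaterms) {
    n <- length(metaterms)
    tibble::tibble(metaterm = metaterms, count = rev(seq_len(n)),
                   weight = rev(seq_len(n)) / sum(seq_len(n)) * 100,
                   rank = seq_len(n))
  }
  a <- mk(c("cardio", "neuro", "genetics", "surgery"))
  b <- mk(c("neuro", "cardio", "ethics", "law"))
  expect_equal(top_n_overlap(list(a, a), 3), c("cardio", "genetics", "neuro"))
  expect_equal(top_n_overlap(list(a, b), 2), c("cardio", "neuro"))
  expect_equal(top_n_overlap(list(mk(c("x", "y")), mk(c("p", "q"))), 2),
               character())
  long <- mk(c("cardio", "neuro", paste0("m", 1:8)))
  expect_warning(top_n_overlap(list(a, long), 10), "only 4 rows")
  # brute-force membership oracle on random tables
  for (seed in 1:20) {
    set.seed(seed)
    tabs <- lapply(1:3, function(i) mk(sample(letters[1:8], 6)))
    n <- sample(1:6, 1)
    want <- character()
    for (m in letters[1:8]) {
      if (all(vapply(tabs, function(t) m %in% t$metaterm[seq_len(n)], TRUE))) {
        want <- c(want, m)
      }
    }
    expect_equal(top_n_overlap(tabs, n), sort(want))
  }
})

test_that("the report bundle is cross-consistent and deterministic", {
  cfg <- generator_config(seed = 8, journals = c("BMJ", "JAMA", "Lancet"),
                          years = c(1997L, 2007L), n_articles_per_cell = 50,
                          n_specialties = 4, branching = 4, tree_depth = 2)
  toy <- generate_toy_thesaurus(cfg)
  corp <- generate_corpus(cfg, toy)
  rep <- build_report(corp, toy$thesaurus, toy$links)
  expect_length(rep$profiles, 6)
  expect_length(rep$pooled, 3)
  expect_equal(length(unique(rep$trends$journal)), 3)

  # trend inputs equal the stored profile weights
  for (i in seq_len(nrow(rep$trends))) {
    tr <- rep$trends[i, ]
    p0 <- rep$profiles[[sprintf("%s|%d", tr$journal, tr$year_start)]]$table
    w0 <- p0$weight[match(tr$metaterm, p0$metaterm)]
    expect_equal(tr$weight_start, ifelse(is.na(w0), 0, w0))
    if (tr$weight_start > 0) {
      expect_equal(tr$trend_percent,
                   trend_percent(tr$weight_start, tr$weight_end))
    }
  }

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(build_report(generate_corpus(cfg, toy), toy$thesaurus,
                            toy$links), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  md <- readLines(file.path(d1, "report.md"))
  expect_true(any(grepl("^\\| Specialty \\|", md)))
})
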