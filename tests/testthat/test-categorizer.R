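cf <- curated_fixture()

test_that("single-heading induction covers direct, ancestor and qualifier routes", {
  # direct + ancestor routes collapse to the same specialty sets
  expect_equal(induce_for_heading("Thumb", thesaurus = cf$thesaurus,
                                  links = cf$links), "anatomy")
  expect_equal(induce_for_heading("Alcoholism", thesaurus = cf$thesaurus,
                                  links = cf$links),
               c("psychiatry", "toxicology"))
  # closure-only descriptors (no direct link anywhere on them)
  expect_equal(induce_for_heading("Fingers", thesaurus = cf$thesaurus,
                                  links = cf$links), "anatomy")
  expect_equal(induce_for_heading("Substance-Related Disorders",
                                  thesaurus = cf$thesaurus, links = cf$links),
               c("psychiatry", "toxicology"))
  # qualifier contributes only when present and major
  expect_equal(induce_for_heading("Thumb", "therapy", qualifier_major = TRUE,
                                  thesaurus = cf$thesaurus, links = cf$links),
               c("anatomy", "therapeutics"))
  expect_equal(induce_for_heading("Thumb", "therapy", qualifier_major = FALSE,
                                  thesaurus = cf$thesaurus, links = cf$links),
               "anatomy")
  expect_warning(
    out <- induce_for_heading("Unknown Term", thesaurus = cf$thesaurus,
                              links = cf$links),
    "unresolvable")
  expect_equal(out, character())
})

test_that("article categorization counts supporting headings and ranks", {
  corp <- parse_medline_text(c(
    "PMID- 1", "JT  - Lancet", "DP  - 1997",
    "MH  - *Alcoholism", "MH  - *Mental Disorders", "MH  - *Thumb",
    "MH  - Hand", "",
    "PMID- 2", "JT  - Lancet", "DP  - 1997",
    "MH  - Thumb", "MH  - Fingers", ""))
  res <- categorize_article(corp, "1", cf$thesaurus, cf$links)
  expect_equal(res$metaterm, c("psychiatry", "anatomy", "toxicology"))
  expect_equal(res$support, c(2L, 1L, 1L))
  # article 2 has no major headings at all
  expect_equal(nrow(categorize_article(corp, "2", cf$thesaurus, cf$links)), 0)
})

test_that("excluded metaterms are dropped post-induction, pre-ranking", {
  corp <- parse_medline_text(c(
    "PMID- 1", "JT  - BMJ", "DP  - 1997",
    "MH  - *Statistics as Topic", ""))
  expect_equal(nrow(categorize_corpus(corp, cf$thesaurus, cf$links)), 0)
  diag <- categorize_corpus(corp, cf$thesaurus, cf$links,
                            drop_excluded = FALSE)
  expect_equal(diag$metaterm, "statistics")
})

test_that("corpus categorization equals the brute-force closure oracle", {
  for (seed in 1:30) {
    toy <- random_toy_thesaurus(seed)
    corp <- random_toy_corpus(seed, toy$thesaurus)
    got <- categorize_corpus(corp, toy$thesaurus, toy$links)
    want <- oracle_categorize(corp, toy$thesaurus, toy$links)
    expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("adding a major heading never decreases any support count", {
  toy <- random_toy_thesaurus(3)
  corp <- random_toy_corpus(3, toy$thesaurus, n_articles = 8)
  base <- categorize_corpus(corp, toy$thesaurus, toy$links)
  for (extra in toy$thesaurus$descriptors$name[1:5]) {
    h2 <- dplyr::bind_rows(
      corp$headings,
      tibble::tibble(article_id = corp$articles$article_id[1],
                     descriptor = extra, qualifier = NA_character_,
                     descriptor_major = TRUE, qualifier_major = FALSE))
    grown <- categorize_corpus(
      medline_corpus(corp$articles, h2), toy$thesaurus, toy$links)
    joined <- dplyr::left_join(base, grown,
                               by = c("article_id", "metaterm"),
                               suffix = c("_base", "_grown"))
    expect_true(all(joined$support_grown >= joined$support_base))
  }
})

test_that("a new link reaches every article with the descriptor or a descendant", {
  toy <- random_toy_thesaurus(5)
  corp <- random_toy_corpus(5, toy$thesaurus, n_articles = 12)
  d <- toy$thesaurus$descriptors
  target <- d$id[1]
  below <- c(target, vapply(d$id, function(x)
    if (target %in% oracle_ancestors(x, toy$thesaurus)) x else NA_character_,
    ""))
  below_names <- d$name[d$id %in% below[!is.na(below)]]
  links2 <- metaterm_links(dplyr::bind_rows(
    toy$links$links,
    tibble::tibble(metaterm = "newspecialty", target_id = target,
                   target_kind = "descriptor")))
  res <- categorize_corpus(corp, toy$thesaurus, links2)
  mh <- major_headings(corp)
  hit_articles <- unique(mh$article_id[mh$descriptor %in% below_names])
  with_new <- unique(res$article_id[res$metaterm == "newspecialty"])
  expect_setequal(with_new, hit_articles)
})

test_that("categorization is deterministic and order-stable", {
  toy <- random_toy_thesaurus(9)
  corp <- random_toy_corpus(9, toy$thesaurus, n_articles = 10)
  r1 <- categorize_corpus(corp, toy$thesaurus, toy$links)
  r2 <- categorize_corpus(corp, toy$thesaurus, toy$links)
  expect_identical(r1, r2)
  # results come back in corpus article order, rank order within article
  ord <- match(r1$article_id, corp$articles$article_id)
  expect_true(all(diff(ord) >= 0))
})

test_that("categorization files render as TSV and JSON lines", {
  corp <- parse_medline_text(c(
    "PMID- 1", "JT  - BMJ", "DP  - 1997",
    "MH  - *Alcoholism", "MH  - *Thumb", ""))
  res <- categorize_corpus(corp, cf$thesaurus, cf$links)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_categorization(res, tsv)
  lines <- readLines(tsv)
  expect_equal(lines[1], "article_id\tmetaterm\tsupport")
  expect_equal(length(lines), nrow(res) + 1)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_categorization(res, jl, format = "jsonl")
  parsed <- jsonlite::fromJSON(readLines(jl)[1])
  expect_equal(parsed$article_id, "1")
  expect_equal(parsed$induced$metaterm, res$metaterm)
})
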