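#' Count metaterm occurrences over categorization results
#'
#' The article unit (default) counts a metaterm once per article in which it
#' is induced; the heading unit sums per-heading support counts instead.
#'
#' @param results tibble from [categorize_corpus()].
#' @param unit `"article"` or `"heading"`.
#' @return Tibble with columns `metaterm`, `count`, sorted by metaterm.
#' @export
count_occurrences <- function(results, unit = c("article", "heading")) {
  unit <- match.arg(unit)
  if (nrow(results) == 0) {
    return(tibble::tibble(metaterm = character(), count = integer()))
  }
  out <- if (unit == "article") {
    dplyr::count(dplyr::distinct(results, .data$article_id, .data$metaterm),
                 .data$metaterm, name = "count")
  } else {
    dplyr::summarise(dplyr::group_by(results, .data$metaterm),
                     count = sum(.data$support), .groups = "drop")
  }
  out$count <- as.integer(out$count)
  out <- dplyr::arrange(tibble::as_tibble(out), .data$metaterm)
  # drop bookkeeping attributes inherited from the categorization tibble
  attr(out, "n_unresolved") <- NULL
  attr(out, "unresolved_descriptors") <- NULL
  out
}

#' Relative weight of a specialty
#'
#' The share, in percent, of a metaterm's occurrences among all metaterm
#' occurrences in a profile, reported to two decimals.
#'
#' @param count non-negative occurrence count (vectorized).
#' @param total positive denominator.
#' @param digits decimals for reporting (default 2; `NA` for no rounding).
#' @return Percent value(s).
#' @export
relative_weight <- function(count, total, digits = 2) {
  if (any(total <= 0)) {
    stop("relative weight undefined for a profile with total 0", call. = FALSE)
  }
  w <- count / total * 100
  if (!is.na(digits)) w <- round(w, digits) else w
  w
}

#' Build a journal-year specialty profile
#'
#' Categorizes the articles of one journal in the given year(s) and tallies
#' metaterm occurrences into counts and relative weights. The default
#' denominator is the total number of metaterm occurrences in the cell, so
#' weights sum to 100%; the `"article"` denominator (share of articles
#' mentioning the specialty) is available but does not normalize to 100%.
#'
#' @param corpus a [medline_corpus()].
#' @param thesaurus a [mesh_thesaurus()].
#' @param links a [metaterm_links()] object.
#' @param journal journal label to select.
#' @param years integer vector of years to pool (default: all present).
#' @param unit counting unit, `"article"` or `"heading"`.
#' @param denominator `"occurrence"` (default) or `"article"`.
#' @return An object of class `journal_year_profile`: journal, years, a
#'   table with `metaterm`, `count`, `weight` (unrounded percent), the
#'   denominator `total`, and bookkeeping fields.
#' @export
journal_year_profile <- function(corpus, thesaurus, links, journal,
                                 years = NULL,
                                 unit = c("article", "heading"),
                                 denominator = c("occurrence", "article")) {
  unit <- match.arg(unit)
  denominator <- match.arg(denominator)
  a <- corpus$articles
  keep <- a$journal == journal
  if (!is.null(years)) keep <- keep & a$year %in% years
  ids <- a$article_id[keep]
  sub <- medline_corpus(a[keep, , drop = FALSE],
                        corpus$headings[corpus$headings$article_id %in% ids, ,
                                        drop = FALSE],
                        provenance = corpus$provenance)
  results <- categorize_corpus(sub, thesaurus, links)
  profile_from_results(results, journal = journal,
                       years = if (is.null(years)) sort(unique(a$year[keep]))
                               else sort(unique(as.integer(years))),
                       unit = unit, denominator = denominator,
                       n_articles = length(ids))
}

# shared constructor so build_report can categorize the corpus once
profile_from_results <- function(results, journal, years, unit, denominator,
                                 n_articles) {
  counts <- count_occurrences(results, unit = unit)
  total <- if (denominator == "occurrence") sum(counts$count) else n_articles
  if (total > 0) {
    counts$weight <- relative_weight(counts$count, total, digits = NA)
  } else {
    counts$weight <- numeric(nrow(counts))
  }
  structure(list(journal = journal, years = as.integer(years),
                 table = counts, total = as.integer(total),
                 unit = unit, denominator = denominator,
                 n_articles = as.integer(n_articles)),
            class = "journal_year_profile")
}

#' @export
print.journal_year_profile <- function(x, ...) {
  cat(sprintf("<journal_year_profile> %s [%s]: %d metaterms, total %d (%s unit, %s denominator)\n",
              x$journal, paste(x$years, collapse = ","), nrow(x$table),
              x$total, x$unit, x$denominator))
  invisible(x)
}

#' Rank the metaterms of a profile
#'
#' Ranks run 1, 2, 3, ... by weight descending with alphabetical tie-break
#' (tied weights get distinct consecutive ranks in name order, matching the
#' printed "%/R" table style).
#'
#' @param profile a [journal_year_profile()].
#' @param top_n optionally truncate to the first `top_n` rows.
#' @return Tibble with columns `metaterm`, `count`, `weight`, `rank`.
#' @export
rank_metaterms <- function(profile, top_n = NULL) {
  stopifnot(inherits(profile, "journal_year_profile"))
  tab <- profile$table
  if (nrow(tab) == 0) stop("cannot rank an empty profile", call. = FALSE)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$weight), .data$metaterm)
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(top_n)) tab <- head(tab, top_n)
  tab
}

#' Percent trend between two relative weights
#'
#' Signed integer percent change `(end - start) / start * 100`, rounded
#' half away from zero (so 75.62 prints as 76, -75.62 as -76). Undefined
#' when the starting weight is zero.
#'
#' @param weight_start,weight_end percent weights (vectorized).
#' @return Integer vector of signed percent trends.
#' @export
trend_percent <- function(weight_start, weight_end) {
  if (any(weight_start <= 0)) {
    stop("trend undefined when the starting weight is 0", call. = FALSE)
  }
  x <- (weight_end - weight_start) / weight_start * 100
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Pool several profiles into one
#'
#' Counts are summed metaterm-wise across the inputs and weights recomputed
#' from the pooled denominator (the Table-1-style "years cumulated" view).
#' Inputs must share the counting unit and denominator mode; pooling across
#' different journals requires `cross_journal = TRUE` and labels the result
#' `"all"`.
#'
#' @param profiles list of [journal_year_profile()] objects.
#' @param cross_journal allow pooling across journals.
#' @return A [journal_year_profile()].
#' @export
pooled_profile <- function(profiles, cross_journal = FALSE) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "journal_year_profile")))
  units <- unique(vapply(profiles, `[[`, "", "unit"))
  denoms <- unique(vapply(profiles, `[[`, "", "denominator"))
  if (length(units) > 1 || length(denoms) > 1) {
    stop("cannot pool profiles with mixed counting units or denominators",
         call. = FALSE)
  }
  journals <- unique(vapply(profiles, `[[`, "", "journal"))
  if (length(journals) > 1 && !cross_journal) {
    stop("profiles span several journals; set cross_journal = TRUE to pool",
         call. = FALSE)
  }
  counts <- dplyr::summarise(
    dplyr::group_by(
      dplyr::bind_rows(lapply(profiles, function(p) p$table[c("metaterm", "count")])),
      .data$metaterm),
    count = sum(.data$count), .groups = "drop"
  )
  counts$count <- as.integer(counts$count)
  res <- tibble::tibble(article_id = character(), metaterm = character(),
                        support = integer())
  p <- profile_from_results(res,
    journal = if (length(journals) == 1) journals else "all",
    years = sort(unique(unlist(lapply(profiles, `[[`, "years")))),
    unit = units, denominator = denoms,
    n_articles = sum(vapply(profiles, `[[`, 1L, "n_articles")))
  p$table <- dplyr::arrange(counts, .data$metaterm)
  p$total <- if (denoms == "occurrence") sum(counts$count) else p$n_articles
  if (p$total > 0) {
    p$table$weight <- relative_weight(p$table$count, p$total, digits = NA)
  } else {
    p$table$weight <- numeric(nrow(p$table))
  }
  p
}

#' Metaterms in the top N of every ranked table
#'
#' Exact intersection of the top-`n` metaterm sets of several ranked tables
#' (the "systematically ranked in the first 10" summary). A table shorter
#' than `n` contributes its full set, with a warning.
#'
#' @param tables list of ranked tables from [rank_metaterms()].
#' @param n top-list depth.
#' @return Sorted character vector of shared metaterms.
#' @export
top_n_overlap <- function(tables, n) {
  stopifnot(length(tables) >= 2, n >= 1)
  sets <- lapply(tables, function(tab) {
    if (nrow(tab) < n) {
      warning(sprintf("ranked table has only %d rows (< n = %d); using all",
                      nrow(tab), n), call. = FALSE)
    }
    head(tab$metaterm, n)
  })
  sort(Reduce(intersect, sets))
}
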