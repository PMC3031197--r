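#' Run the full journal-profiling analysis
#'
#' Orchestrates one pass over a corpus: categorize every article, build one
#' profile per journal-year cell, pool years into per-journal tables, rank,
#' compute start-to-end-year trends for each journal's leading metaterms,
#' and summarize cross-journal top-N overlaps. All tables derive from a
#' single categorization pass, so trend inputs equal profile weights by
#' construction.
#'
#' @param corpus a [medline_corpus()].
#' @param thesaurus a [mesh_thesaurus()].
#' @param links a [metaterm_links()] object.
#' @param unit counting unit, `"article"` (default) or `"heading"`.
#' @param denominator `"occurrence"` (default) or `"article"`.
#' @param top_n_table rows kept in ranked tables (default 30).
#' @param top_n_trend metaterms per journal in the trend table (default 15),
#'   chosen by pooled weight.
#' @param overlap_ns depths for the cross-journal overlap summary.
#' @return An object of class `metaterm_report` with elements `profiles`
#'   (per journal-year cell), `pooled` (per journal, years cumulated),
#'   `pooled_all`, `ranked` (per journal), `trends` (tibble `journal`,
#'   `metaterm`, `weight_start`, `weight_end`, `trend_percent`), `overlap`
#'   (list depth -> shared metaterm set), and `stats` (audit counts).
#' @export
build_report <- function(corpus, thesaurus, links,
                         unit = c("article", "heading"),
                         denominator = c("occurrence", "article"),
                         top_n_table = 30, top_n_trend = 15,
                         overlap_ns = c(10, 20, 30)) {
  unit <- match.arg(unit)
  denominator <- match.arg(denominator)
  results <- categorize_corpus(corpus, thesaurus, links)
  a <- corpus$articles

  stats <- list(
    articles = nrow(a),
    headings = nrow(corpus$headings),
    major_headings = nrow(major_headings(corpus)),
    unresolved_headings = attr(results, "n_unresolved"),
    induced_occurrences = nrow(results),
    induced_support = sum(results$support),
    metaterms = length(unique(results$metaterm))
  )

  cells <- dplyr::distinct(a, .data$journal, .data$year)
  cells <- dplyr::arrange(cells, .data$journal, .data$year)
  profiles <- vector("list", nrow(cells))
  names(profiles) <- sprintf("%s|%d", cells$journal, cells$year)
  for (i in seq_len(nrow(cells))) {
    ids <- a$article_id[a$journal == cells$journal[i] & a$year == cells$year[i]]
    profiles[[i]] <- profile_from_results(
      results[results$article_id %in% ids, , drop = FALSE],
      journal = cells$journal[i], years = cells$year[i],
      unit = unit, denominator = denominator, n_articles = length(ids))
  }

  journals <- sort(unique(cells$journal))
  pooled <- lapply(journals, function(j) {
    pooled_profile(profiles[cells$journal == j])
  })
  names(pooled) <- journals
  pooled_all <- pooled_profile(unname(pooled), cross_journal = TRUE)

  ranked <- lapply(pooled, rank_metaterms, top_n = top_n_table)

  # trends: first vs last year, per journal, for the pooled-top metaterms
  trends <- lapply(journals, function(j) {
    yrs <- sort(cells$year[cells$journal == j])
    if (length(yrs) < 2) return(NULL)
    top <- head(rank_metaterms(pooled[[j]])$metaterm, top_n_trend)
    p0 <- profiles[[sprintf("%s|%d", j, yrs[1])]]$table
    p1 <- profiles[[sprintf("%s|%d", j, yrs[length(yrs)])]]$table
    w0 <- p0$weight[match(top, p0$metaterm)]
    w1 <- p1$weight[match(top, p1$metaterm)]
    w0[is.na(w0)] <- 0
    w1[is.na(w1)] <- 0
    tp <- rep(NA_integer_, length(top))
    ok <- w0 > 0
    if (any(ok)) tp[ok] <- trend_percent(w0[ok], w1[ok])
    tibble::tibble(
      journal = j, metaterm = top,
      year_start = yrs[1], year_end = yrs[length(yrs)],
      weight_start = w0, weight_end = w1,
      trend_percent = tp
    )
  })
  trends <- dplyr::bind_rows(trends)

  overlap <- list()
  if (length(journals) >= 2) {
    full_ranked <- lapply(pooled, rank_metaterms)
    for (n in overlap_ns) {
      overlap[[as.character(n)]] <-
        suppressWarnings(top_n_overlap(full_ranked, n))
    }
  }

  structure(list(profiles = profiles, pooled = pooled, pooled_all = pooled_all,
                 ranked = ranked, trends = trends, overlap = overlap,
                 stats = stats, unit = unit, denominator = denominator),
            class = "metaterm_report")
}

#' @export
print.metaterm_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<metaterm_report> %d articles, %d major headings, %d metaterms induced (%d occurrences)\n",
              s$articles, s$major_headings, s$metaterms, s$induced_occurrences))
  cat(sprintf("  %d journal-year profiles, %d journals, %d trend rows\n",
              length(x$profiles), length(x$pooled), nrow(x$trends)))
  invisible(x)
}

profile_csv_lines <- function(profile) {
  tab <- rank_metaterms(profile)
  c("metaterm,count,weight_percent,rank",
    sprintf("%s,%d,%.2f,%d", tab$metaterm, tab$count, tab$weight, tab$rank))
}

#' Write a report bundle to a directory
#'
#' Emits one CSV per journal-year profile and per pooled journal table
#' (`metaterm,count,weight_percent,rank`), a trend CSV
#' (`journal,metaterm,weight_start,weight_end,trend_percent`), a plain-text
#' overlap summary, a Markdown rendering of the cumulated rankings, and a
#' JSON run summary with the audit counts.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "metaterm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(x) gsub("[^A-Za-z0-9_-]+", "_", x)

  for (nm in names(report$profiles)) {
    p <- report$profiles[[nm]]
    if (nrow(p$table) == 0) next
    writeLines(profile_csv_lines(p),
               file.path(dir, sprintf("profile_%s.csv", safe(nm))))
  }
  for (j in names(report$pooled)) {
    writeLines(profile_csv_lines(report$pooled[[j]]),
               file.path(dir, sprintf("pooled_%s.csv", safe(j))))
  }

  tr <- report$trends
  writeLines(c("journal,metaterm,weight_start,weight_end,trend_percent",
               if (nrow(tr) > 0)
                 sprintf("%s,%s,%.2f,%.2f,%s", tr$journal, tr$metaterm,
                         tr$weight_start, tr$weight_end,
                         ifelse(is.na(tr$trend_percent), "NA",
                                sprintf("%+d", tr$trend_percent)))),
             file.path(dir, "trends.csv"))

  ov <- vapply(names(report$overlap), function(n) {
    sprintf("top-%s shared by all journals (%d): %s", n,
            length(report$overlap[[n]]),
            paste(report$overlap[[n]], collapse = ", "))
  }, "")
  writeLines(ov, file.path(dir, "overlap.txt"))

  writeLines(render_markdown_report(report), file.path(dir, "report.md"))
  jsonlite::write_json(report$stats, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Render the cumulated ranking as a Markdown table
#'
#' One row per metaterm (ordered by the all-journal pooled weight), with a
#' weight and rank column pair per journal plus the pooled total — the
#' layout of a printed "distribution and ranking" table.
#'
#' @param report a [build_report()] result.
#' @param top_n rows to print (default 30).
#' @return Character vector of Markdown lines.
#' @export
render_markdown_report <- function(report, top_n = 30) {
  journals <- names(report$pooled)
  all_tab <- rank_metaterms(report$pooled_all, top_n = top_n)
  ranked_full <- lapply(report$pooled, rank_metaterms)

  header <- paste0("| Specialty | ",
                   paste(vapply(journals, function(j)
                     sprintf("%s %% | R", j), ""), collapse = " | "),
                   " | Total % | R |")
  sep <- paste0("|", paste(rep("---|", 2 * length(journals) + 3),
                           collapse = ""))
  rows <- vapply(seq_len(nrow(all_tab)), function(i) {
    m <- all_tab$metaterm[i]
    cells <- vapply(journals, function(j) {
      tab <- ranked_full[[j]]
      k <- match(m, tab$metaterm)
      if (is.na(k)) "- | -" else sprintf("%.2f%% | %d", tab$weight[k], tab$rank[k])
    }, "")
    sprintf("| %s | %s | %.2f%% | %d |", m, paste(cells, collapse = " | "),
            all_tab$weight[i], all_tab$rank[i])
  }, "")
  c(sprintf("## Metaterm distribution, years %s cumulated",
            paste(sort(unique(unlist(lapply(report$profiles, `[[`, "years")))),
                  collapse = "/")),
    "", header, sep, rows)
}
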