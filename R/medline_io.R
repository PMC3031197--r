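#' Construct a corpus of MEDLINE article records
#'
#' A corpus couples an article table (one row per article: id, journal,
#' 4-digit publication year) with a heading table (one row per MeSH heading
#' assignment: descriptor, optional qualifier, and the major-topic flags the
#' NLM indexers set). A heading is "major" when either its descriptor or its
#' qualifier carries the asterisk in MEDLINE display.
#'
#' @param articles tibble with columns `article_id`, `journal`, `year`.
#' @param headings tibble with columns `article_id`, `descriptor`,
#'   `qualifier` (NA when absent), `descriptor_major`, `qualifier_major`.
#' @param provenance free-text source description.
#' @param n_skipped count of records dropped during parsing (missing PMID/DP).
#' @return An object of class `medline_corpus`.
#' @export
medline_corpus <- function(articles, headings, provenance = "in-memory",
                           n_skipped = 0L) {
  articles <- tibble::as_tibble(articles)
  headings <- tibble::as_tibble(headings)
  stopifnot(all(c("article_id", "journal", "year") %in% names(articles)),
            all(c("article_id", "descriptor", "qualifier",
                  "descriptor_major", "qualifier_major") %in% names(headings)))
  if (anyDuplicated(articles$article_id)) {
    stop("duplicate article_id in corpus", call. = FALSE)
  }
  bad_year <- articles$year < 1000 | articles$year > 9999
  if (nrow(articles) > 0 && any(bad_year, na.rm = TRUE)) {
    stop("year must be a 4-digit integer", call. = FALSE)
  }
  if (any(headings$qualifier_major & is.na(headings$qualifier))) {
    stop("qualifier_major set on a heading without a qualifier", call. = FALSE)
  }
  articles$year <- as.integer(articles$year)
  structure(list(articles = articles, headings = headings,
                 provenance = provenance, n_skipped = as.integer(n_skipped)),
            class = "medline_corpus")
}

#' @export
print.medline_corpus <- function(x, ...) {
  cat(sprintf("<medline_corpus> %d articles, %d headings (%d major) [%s]\n",
              nrow(x$articles), nrow(x$headings),
              sum(x$headings$descriptor_major | x$headings$qualifier_major),
              x$provenance))
  if (x$n_skipped > 0) cat(sprintf("  %d record(s) skipped at parse\n", x$n_skipped))
  invisible(x)
}

# "Alcoholism/*therapy" -> one row per (descriptor, qualifier); star marks major
parse_mh_line <- function(value) {
  if (is.na(value) || !nzchar(trimws(value))) {
    return(tibble::tibble(descriptor = character(), qualifier = character(),
                          descriptor_major = logical(),
                          qualifier_major = logical()))
  }
  parts <- strsplit(value, "/", fixed = TRUE)[[1]]
  desc <- parts[1]
  desc_major <- startsWith(desc, "*")
  if (desc_major) desc <- substring(desc, 2)
  quals <- parts[-1]
  if (length(quals) == 0) {
    return(tibble::tibble(descriptor = desc, qualifier = NA_character_,
                          descriptor_major = desc_major, qualifier_major = FALSE))
  }
  qual_major <- startsWith(quals, "*")
  quals[qual_major] <- substring(quals[qual_major], 2)
  tibble::tibble(descriptor = desc, qualifier = quals,
                 descriptor_major = desc_major, qualifier_major = qual_major)
}

#' Parse MEDLINE field-tag text into a corpus
#'
#' Reads the plain-text MEDLINE/nbib dialect: `TAG - value` lines, records
#' separated by blank lines, continuation lines indented six spaces. The
#' journal comes from `JT`, the year from the first four digits of `DP`, the
#' id from `PMID`, and headings from `MH` lines where a `*` prefix on the
#' descriptor or a qualifier sets the corresponding major-topic flag.
#' Records lacking `PMID` or `DP` are skipped with a warning and counted in
#' the corpus's `n_skipped`.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param journal_aliases optional named character vector mapping verbatim
#'   `JT` values to canonical journal labels (e.g.
#'   `c("BMJ (Clinical research ed.)" = "BMJ")`).
#' @param provenance free-text source description.
#' @return A [medline_corpus()].
#' @export
parse_medline_text <- function(text, journal_aliases = NULL,
                               provenance = "medline text") {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  # fold continuation lines (6 leading spaces) into the previous field line
  is_cont <- startsWith(text, "      ") & !grepl("^ *$", text)
  if (any(is_cont)) {
    out <- character(0)
    for (ln in text) {
      if (startsWith(ln, "      ") && length(out) > 0 && nzchar(trimws(ln))) {
        out[length(out)] <- paste0(out[length(out)], " ", trimws(ln))
      } else out <- c(out, ln)
    }
    text <- out
  }

  blank <- !nzchar(trimws(text))
  rec_id <- cumsum(c(TRUE, diff(!blank) == 1))  # record index per line
  rec_id[blank] <- NA
  recs <- split(text[!blank], rec_id[!blank])

  arts <- vector("list", length(recs))
  heads <- vector("list", length(recs))
  n_skipped <- 0L
  for (k in seq_along(recs)) {
    lines <- recs[[k]]
    m <- regmatches(lines, regexec("^([A-Z0-9]{1,4}) *- (.*)$", lines))
    tags <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
    vals <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
    pmid <- vals[which(tags == "PMID")[1]]
    dp <- vals[which(tags == "DP")[1]]
    jt <- vals[which(tags == "JT")[1]]
    year <- if (!is.na(dp)) regmatches(dp, regexpr("\\d{4}", dp)) else character()
    if (is.na(pmid) || length(year) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    journal <- if (is.na(jt)) NA_character_ else jt
    if (!is.null(journal_aliases) && !is.na(journal) &&
        journal %in% names(journal_aliases)) {
      journal <- unname(journal_aliases[journal])
    }
    arts[[k]] <- tibble::tibble(article_id = pmid, journal = journal,
                                year = as.integer(year))
    mh <- vals[which(tags == "MH")]
    if (length(mh) > 0) {
      h <- dplyr::bind_rows(lapply(mh, parse_mh_line))
      h$article_id <- pmid
      heads[[k]] <- h[c("article_id", "descriptor", "qualifier",
                        "descriptor_major", "qualifier_major")]
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("%d record(s) skipped (missing PMID or DP)", n_skipped),
            call. = FALSE)
  }
  articles <- dplyr::bind_rows(arts)
  if (nrow(articles) == 0) {
    articles <- tibble::tibble(article_id = character(), journal = character(),
                               year = integer())
  }
  headings <- dplyr::bind_rows(heads)
  if (nrow(headings) == 0) {
    headings <- tibble::tibble(article_id = character(), descriptor = character(),
                               qualifier = character(),
                               descriptor_major = logical(),
                               qualifier_major = logical())
  }
  medline_corpus(articles, headings, provenance = provenance,
                 n_skipped = n_skipped)
}

#' Read a MEDLINE field-tag export from disk
#'
#' @inheritParams parse_medline_text
#' @param path path to the export file.
#' @return A [medline_corpus()].
#' @export
read_medline <- function(path, journal_aliases = NULL) {
  if (!file.exists(path)) stop("MEDLINE file not found: ", path, call. = FALSE)
  parse_medline_text(readLines(path, encoding = "UTF-8", warn = FALSE),
                     journal_aliases = journal_aliases, provenance = path)
}

#' Render a corpus back to MEDLINE field-tag text
#'
#' Companion writer to [parse_medline_text()]; one `MH` line per heading
#' assignment, records separated by blank lines. `parse(render(x))`
#' reproduces `x` exactly (up to provenance).
#'
#' @param corpus a [medline_corpus()].
#' @return Character vector of lines.
#' @export
render_medline <- function(corpus) {
  stopifnot(inherits(corpus, "medline_corpus"))
  a <- corpus$articles
  h <- corpus$headings
  out <- character(0)
  for (i in seq_len(nrow(a))) {
    hh <- h[h$article_id == a$article_id[i], , drop = FALSE]
    mh <- character(0)
    if (nrow(hh) > 0) {
      desc <- ifelse(hh$descriptor_major, paste0("*", hh$descriptor),
                     hh$descriptor)
      qual <- ifelse(is.na(hh$qualifier), "",
                     paste0("/", ifelse(hh$qualifier_major, "*", ""),
                            hh$qualifier))
      mh <- paste0("MH  - ", desc, qual)
    }
    out <- c(out,
             paste0("PMID- ", a$article_id[i]),
             paste0("JT  - ", a$journal[i]),
             paste0("DP  - ", a$year[i]),
             mh,
             "")
  }
  out
}

#' Write a corpus as a MEDLINE field-tag file
#'
#' @param corpus a [medline_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(corpus, path) {
  writeLines(render_medline(corpus), path, useBytes = TRUE)
  invisible(path)
}

#' Extract the major headings of a corpus
#'
#' A heading is major when its descriptor or its qualifier is starred; these
#' are the T1...Tn the categorizer consumes. Original heading order is
#' preserved within each article.
#'
#' @param corpus a [medline_corpus()].
#' @param article_id optional single id restricting the result to one article.
#' @return Tibble of heading assignments.
#' @export
major_headings <- function(corpus, article_id = NULL) {
  stopifnot(inherits(corpus, "medline_corpus"))
  h <- corpus$headings
  if (!is.null(article_id)) h <- h[h$article_id == article_id, , drop = FALSE]
  h[h$descriptor_major | h$qualifier_major, , drop = FALSE]
}

#' Read a PubMed XML export into a corpus
#'
#' Maps `MeshHeadingList/MeshHeading/DescriptorName[@MajorTopicYN]` and
#' `QualifierName[@MajorTopicYN]` to the same heading model as the field-tag
#' reader. The year is taken from `PubDate/Year` or, failing that, the first
#' four digits of `PubDate/MedlineDate`.
#'
#' @inheritParams read_medline
#' @return A [medline_corpus()].
#' @export
read_pubmed_xml <- function(path, journal_aliases = NULL) {
  if (!file.exists(path)) stop("PubMed XML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  arts_xml <- xml2::xml_find_all(doc, ".//PubmedArticle")
  arts <- vector("list", length(arts_xml))
  heads <- vector("list", length(arts_xml))
  n_skipped <- 0L
  for (k in seq_along(arts_xml)) {
    node <- arts_xml[[k]]
    pmid <- xml2::xml_text(xml2::xml_find_first(node, ".//MedlineCitation/PMID"))
    jt <- xml2::xml_text(xml2::xml_find_first(node, ".//Journal/Title"))
    yr <- xml2::xml_text(xml2::xml_find_first(node, ".//PubDate/Year"))
    if (is.na(yr)) {
      md <- xml2::xml_text(xml2::xml_find_first(node, ".//PubDate/MedlineDate"))
      yr <- if (!is.na(md)) regmatches(md, regexpr("\\d{4}", md)) else NA_character_
      if (length(yr) == 0) yr <- NA_character_
    }
    if (is.na(pmid) || is.na(yr)) { n_skipped <- n_skipped + 1L; next }
    if (!is.null(journal_aliases) && !is.na(jt) && jt %in% names(journal_aliases)) {
      jt <- unname(journal_aliases[jt])
    }
    arts[[k]] <- tibble::tibble(article_id = pmid, journal = jt,
                                year = as.integer(yr))
    mh_nodes <- xml2::xml_find_all(node, ".//MeshHeadingList/MeshHeading")
    if (length(mh_nodes) > 0) {
      rows <- lapply(mh_nodes, function(mh) {
        dn <- xml2::xml_find_first(mh, "./DescriptorName")
        qs <- xml2::xml_find_all(mh, "./QualifierName")
        desc <- xml2::xml_text(dn)
        dmaj <- identical(xml2::xml_attr(dn, "MajorTopicYN"), "Y")
        if (length(qs) == 0) {
          tibble::tibble(descriptor = desc, qualifier = NA_character_,
                         descriptor_major = dmaj, qualifier_major = FALSE)
        } else {
          tibble::tibble(descriptor = desc, qualifier = xml2::xml_text(qs),
                         descriptor_major = dmaj,
                         qualifier_major = xml2::xml_attr(qs, "MajorTopicYN") == "Y")
        }
      })
      h <- dplyr::bind_rows(rows)
      h$article_id <- pmid
      heads[[k]] <- h[c("article_id", "descriptor", "qualifier",
                        "descriptor_major", "qualifier_major")]
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("%d record(s) skipped (missing PMID or year)", n_skipped),
            call. = FALSE)
  }
  articles <- dplyr::bind_rows(arts)
  if (nrow(articles) == 0) {
    articles <- tibble::tibble(article_id = character(), journal = character(),
                               year = integer())
  }
  headings <- dplyr::bind_rows(heads)
  if (nrow(headings) == 0) {
    headings <- tibble::tibble(article_id = character(), descriptor = character(),
                               qualifier = character(),
                               descriptor_major = logical(),
                               qualifier_major = logical())
  }
  medline_corpus(articles, headings, provenance = path, n_skipped = n_skipped)
}
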