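#' Descriptor-to-metaterm closure over the MeSH hierarchy
#'
#' A semantic link placed on a descriptor is inherited downward: any
#' descriptor located below the linked one in the tree (by tree-number
#' prefix) induces the same metaterm. This function materializes that
#' closure once, mapping every descriptor to the union of metaterms linked
#' to itself or to any of its ancestors, so that corpus categorization is a
#' join rather than a per-heading tree walk.
#'
#' @param thesaurus a [mesh_thesaurus()].
#' @param links a [metaterm_links()] object.
#' @return Tibble with columns `descriptor_id`, `descriptor_name`,
#'   `metaterm` (distinct rows).
#' @export
metaterm_closure <- function(thesaurus, links) {
  stopifnot(inherits(thesaurus, "mesh_thesaurus"),
            inherits(links, "metaterm_links"))
  idx <- thesaurus$tree_index
  # (tree position, prefix-or-self) pairs
  pref <- lapply(idx$tree_number, function(tn) c(tree_prefixes(tn), tn))
  pairs <- tibble::tibble(
    self_id = rep(idx$id, times = lengths(pref)),
    anc_tn = unlist(pref, use.names = FALSE)
  )
  pairs <- dplyr::inner_join(pairs, idx, by = c(anc_tn = "tree_number"),
                             relationship = "many-to-one")
  # pairs$id is now the ancestor-or-self descriptor id
  dl <- links$links[links$links$target_kind == "descriptor",
                    c("target_id", "metaterm")]
  out <- dplyr::inner_join(pairs, dl, by = c(id = "target_id"),
                           relationship = "many-to-many")
  out <- dplyr::distinct(out, descriptor_id = .data$self_id, .data$metaterm)
  d <- thesaurus$descriptors
  out$descriptor_name <- d$name[match(out$descriptor_id, d$id)]
  dplyr::arrange(out[c("descriptor_id", "descriptor_name", "metaterm")],
                 .data$descriptor_id, .data$metaterm)
}

qualifier_link_map <- function(thesaurus, links) {
  ql <- links$links[links$links$target_kind == "qualifier",
                    c("target_id", "metaterm")]
  q <- thesaurus$qualifiers
  ql$qualifier_name <- q$name[match(ql$target_id, q$id)]
  ql <- ql[!is.na(ql$qualifier_name), c("qualifier_name", "metaterm")]
  dplyr::distinct(ql)
}

#' Metaterms induced by a single major MeSH heading
#'
#' The induced set is the union of (i) metaterms directly linked to the
#' heading's descriptor, (ii) metaterms linked to any ancestor of the
#' descriptor (the recursive hierarchy step), and (iii) metaterms directly
#' linked to the qualifier, when a qualifier is present and itself major.
#' Exclusion of methods metaterms happens later, at ranking time, so this
#' set is the raw induction.
#'
#' @param descriptor descriptor name (as printed on the `MH` line).
#' @param qualifier qualifier name or `NA`.
#' @param qualifier_major whether the qualifier carries the asterisk.
#' @param thesaurus a [mesh_thesaurus()].
#' @param links a [metaterm_links()] object.
#' @return Character vector of metaterm names (sorted); empty with a warning
#'   when the descriptor cannot be resolved in the thesaurus.
#' @export
induce_for_heading <- function(descriptor, qualifier = NA_character_,
                               qualifier_major = FALSE, thesaurus, links) {
  d <- thesaurus$descriptors
  i <- match(descriptor, d$name)
  if (is.na(i)) {
    warning("unresolvable descriptor: ", descriptor, call. = FALSE)
    return(character())
  }
  targets <- c(d$id[i], mesh_ancestors(d$id[i], thesaurus))
  dl <- links$links[links$links$target_kind == "descriptor", , drop = FALSE]
  induced <- dl$metaterm[dl$target_id %in% targets]
  if (!is.na(qualifier) && isTRUE(qualifier_major)) {
    q <- thesaurus$qualifiers
    qid <- q$id[match(qualifier, q$name)]
    if (!is.na(qid)) {
      induced <- c(induced, linked_metaterms(qid, "qualifier", links))
    }
  }
  sort(unique(induced))
}

#' Categorize every article of a corpus into ranked metaterms
#'
#' For each article with major headings T1...Tn, induces metaterms per
#' heading (see [induce_for_heading()]) and ranks the union M1...Mk by
#' support count — the number of major heading lines inducing the metaterm —
#' descending, ties broken alphabetically. Metaterms on the link table's
#' exclusion list are removed before ranking (set `drop_excluded = FALSE`
#' for diagnostics). Articles with no major headings yield no rows.
#'
#' @param corpus a [medline_corpus()].
#' @param thesaurus a [mesh_thesaurus()].
#' @param links a [metaterm_links()] object.
#' @param drop_excluded drop excluded metaterms before ranking (default TRUE).
#' @return Tibble with columns `article_id`, `metaterm`, `support`, ordered
#'   by corpus article order then rank. Attributes: `n_unresolved` (count of
#'   major headings whose descriptor is not in the thesaurus) and
#'   `unresolved_descriptors` (their names). A warning reports the tally
#'   when it is non-zero.
#' @export
categorize_corpus <- function(corpus, thesaurus, links, drop_excluded = TRUE) {
  stopifnot(inherits(corpus, "medline_corpus"))
  mh <- major_headings(corpus)
  empty <- tibble::tibble(article_id = character(), metaterm = character(),
                          support = integer())
  if (nrow(mh) == 0) {
    attr(empty, "n_unresolved") <- 0L
    attr(empty, "unresolved_descriptors") <- character()
    return(empty)
  }
  mh$h_idx <- seq_len(nrow(mh))

  resolvable <- mh$descriptor %in% thesaurus$descriptors$name
  unresolved <- unique(mh$descriptor[!resolvable])
  n_unresolved <- sum(!resolvable)
  if (n_unresolved > 0) {
    warning(sprintf("%d major heading(s) with unresolvable descriptor(s)",
                    n_unresolved), call. = FALSE)
  }

  closure <- metaterm_closure(thesaurus, links)
  d_ind <- dplyr::inner_join(
    mh[resolvable, c("article_id", "h_idx", "descriptor")],
    closure[c("descriptor_name", "metaterm")],
    by = c(descriptor = "descriptor_name"),
    relationship = "many-to-many"
  )
  qmap <- qualifier_link_map(thesaurus, links)
  q_rows <- mh[resolvable & mh$qualifier_major & !is.na(mh$qualifier),
               c("article_id", "h_idx", "qualifier")]
  q_ind <- dplyr::inner_join(q_rows, qmap,
                             by = c(qualifier = "qualifier_name"),
                             relationship = "many-to-many")

  ind <- dplyr::distinct(dplyr::bind_rows(
    d_ind[c("article_id", "h_idx", "metaterm")],
    q_ind[c("article_id", "h_idx", "metaterm")]
  ))
  if (drop_excluded) {
    ind <- ind[!(ind$metaterm %in% links$excluded_metaterms), , drop = FALSE]
  }
  if (nrow(ind) == 0) {
    res <- empty
  } else {
    res <- dplyr::count(ind, .data$article_id, .data$metaterm,
                        name = "support")
    res$support <- as.integer(res$support)
    ord <- match(res$article_id, corpus$articles$article_id)
    res <- res[order(ord, -res$support, res$metaterm), , drop = FALSE]
    res <- tibble::as_tibble(res)
  }
  attr(res, "n_unresolved") <- as.integer(n_unresolved)
  attr(res, "unresolved_descriptors") <- unresolved
  res
}

#' Categorize a single article
#'
#' Convenience wrapper around [categorize_corpus()] for one article.
#'
#' @inheritParams categorize_corpus
#' @param article_id id of the article to categorize.
#' @return Tibble with columns `metaterm`, `support`, ranked by support
#'   descending then name.
#' @export
categorize_article <- function(corpus, article_id, thesaurus, links,
                               drop_excluded = TRUE) {
  stopifnot(article_id %in% corpus$articles$article_id)
  sub <- medline_corpus(
    corpus$articles[corpus$articles$article_id == article_id, , drop = FALSE],
    corpus$headings[corpus$headings$article_id == article_id, , drop = FALSE],
    provenance = corpus$provenance
  )
  res <- categorize_corpus(sub, thesaurus, links, drop_excluded = drop_excluded)
  res[c("metaterm", "support")]
}

#' Write per-article categorization results
#'
#' Tab-separated `article_id<TAB>metaterm<TAB>support` with header, or a
#' JSON-lines stream (one object per article with its ranked metaterm list).
#'
#' @param results tibble from [categorize_corpus()].
#' @param path output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_categorization <- function(results, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- c("article_id\tmetaterm\tsupport",
              sprintf("%s\t%s\t%d", results$article_id, results$metaterm,
                      results$support))
    writeLines(rows, path, useBytes = TRUE)
  } else {
    by_art <- split(results[c("metaterm", "support")], results$article_id)
    # preserve first-appearance (corpus) order
    by_art <- by_art[unique(results$article_id)]
    lines <- vapply(names(by_art), function(id) {
      jsonlite::toJSON(list(article_id = id,
                            induced = by_art[[id]]),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
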