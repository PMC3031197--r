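# Independent brute-force oracles, deliberately naive: pairwise prefix
# scans and per-heading loops, sharing no code path with the package's
# join-based closure.

oracle_ancestors <- function(id, thesaurus) {
  d <- thesaurus$descriptors
  i <- match(id, d$id)
  anc <- character()
  for (j in seq_len(nrow(d))) {
    if (j == i) next
    for (a in d$tree_numbers[[j]]) {
      for (b in d$tree_numbers[[i]]) {
        if (startsWith(b, paste0(a, "."))) anc <- c(anc, d$id[j])
      }
    }
  }
  sort(unique(anc))
}

oracle_induce <- function(descriptor_name, qualifier, qualifier_major,
                          thesaurus, links) {
  d <- thesaurus$descriptors
  i <- match(descriptor_name, d$name)
  if (is.na(i)) return(character())
  targets <- c(d$id[i], oracle_ancestors(d$id[i], thesaurus))
  out <- character()
  tab <- links$links
  for (r in seq_len(nrow(tab))) {
    if (tab$target_kind[r] == "descriptor" && tab$target_id[r] %in% targets) {
      out <- c(out, tab$metaterm[r])
    }
  }
  if (!is.na(qualifier) && isTRUE(qualifier_major)) {
    q <- thesaurus$qualifiers
    qid <- q$id[match(qualifier, q$name)]
    for (r in seq_len(nrow(tab))) {
      if (!is.na(qid) && tab$target_kind[r] == "qualifier" &&
          tab$target_id[r] == qid) {
        out <- c(out, tab$metaterm[r])
      }
    }
  }
  sort(unique(out))
}

# per-article ranked (metaterm, support) recomputation, heading by heading
oracle_categorize <- function(corpus, thesaurus, links,
                              drop_excluded = TRUE) {
  h <- corpus$headings
  h <- h[h$descriptor_major | h$qualifier_major, , drop = FALSE]
  rows <- list()
  for (aid in corpus$articles$article_id) {
    hh <- h[h$article_id == aid, , drop = FALSE]
    tally <- list()
    for (r in seq_len(nrow(hh))) {
      ms <- oracle_induce(hh$descriptor[r], hh$qualifier[r],
                          hh$qualifier_major[r], thesaurus, links)
      if (drop_excluded) ms <- setdiff(ms, links$excluded_metaterms)
      for (m in ms) tally[[m]] <- (tally[[m]] %||% 0L) + 1L
    }
    if (length(tally) == 0) next
    tab <- tibble::tibble(article_id = aid, metaterm = names(tally),
                          support = as.integer(unlist(tally)))
    tab <- tab[order(-tab$support, tab$metaterm), ]
    rows[[aid]] <- tab
  }
  if (length(rows) == 0) {
    return(tibble::tibble(article_id = character(), metaterm = character(),
                          support = integer()))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random, possibly ragged toy tree (not the package generator): random
# tree numbers built by extending random existing codes
random_toy_thesaurus <- function(seed, n_desc = 20, n_metaterms = 4) {
  set.seed(seed)
  codes <- sprintf("R%02d", seq_len(sample(2:4, 1)))
  while (length(codes) < n_desc) {
    parent <- sample(codes, 1)
    child <- paste0(parent, ".", sprintf("%03d", sample(1:999, 1)))
    if (!child %in% codes) codes <- c(codes, child)
  }
  descriptors <- tibble::tibble(
    id = sprintf("RD%03d", seq_along(codes)),
    name = paste("Rnd", codes),
    tree_numbers = as.list(codes)
  )
  # a few descriptors get a second tree position
  extra <- sample(seq_along(codes), min(3, length(codes)))
  for (k in extra) {
    alt <- paste0(sample(codes, 1), ".", sprintf("%03d", sample(1:999, 1)))
    if (!alt %in% unlist(descriptors$tree_numbers)) {
      descriptors$tree_numbers[[k]] <- c(descriptors$tree_numbers[[k]], alt)
    }
  }
  th <- mesh_thesaurus(descriptors)
  links <- metaterm_links(tibble::tibble(
    metaterm = sprintf("mt%02d", sample(seq_len(n_metaterms),
                                        n_metaterms + 2, replace = TRUE)),
    target_id = sample(descriptors$id, n_metaterms + 2, replace = TRUE),
    target_kind = "descriptor"
  ))
  list(thesaurus = th, links = links)
}

random_toy_corpus <- function(seed, thesaurus, n_articles = 5) {
  set.seed(seed + 10000)
  nms <- thesaurus$descriptors$name
  arts <- tibble::tibble(article_id = sprintf("A%04d", seq_len(n_articles)),
                         journal = sample(c("J1", "J2"), n_articles, TRUE),
                         year = sample(c(1997L, 2007L), n_articles, TRUE))
  heads <- lapply(seq_len(n_articles), function(i) {
    k <- sample(1:6, 1)
    tibble::tibble(article_id = arts$article_id[i],
                   descriptor = sample(nms, k, replace = TRUE),
                   qualifier = NA_character_,
                   descriptor_major = runif(k) < 0.6,
                   qualifier_major = FALSE)
  })
  medline_corpus(arts, dplyr::bind_rows(heads))
}
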