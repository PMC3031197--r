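specialty_name_pool <- c(
  "cardiology", "neurology", "public health", "cancerology",
  "infectious diseases", "epidemiology", "immunology", "vascular medicine",
  "hematology", "surgery", "gastroenterology", "pulmonary disease",
  "genetics", "pediatrics", "information science", "economics",
  "gynecology", "obstetrics", "endocrinology", "rheumatology",
  "risk management", "nutrition", "law", "ethics", "forensic medicine",
  "education", "urology", "addiction", "dermatology", "nephrology"
)

#' Configuration for the synthetic-corpus generator
#'
#' Defaults emulate the study corpus this package was designed around: four
#' general-medicine journals, three publication years ten years apart,
#' roughly 1,174 articles per journal-year (14,088 in total), 8-12 MeSH
#' headings per article of which about 15.7% are major — matching the
#' observed 22,155 major among 141,474 headings over 14,091 articles. The
#' specialty mixture gives, per journal-year cell, the probability that an
#' article's major topic falls in each specialty; when not supplied, one
#' mixture per cell is drawn flat-Dirichlet from `seed` (emulating journals
#' with differing editorial emphases and drifting year profiles).
#'
#' @param seed integer RNG seed for all generator randomness.
#' @param journals character vector of journal labels.
#' @param years integer vector of publication years.
#' @param n_articles_per_cell articles per journal-year cell.
#' @param n_specialties number of planted specialties (each gets a disjoint
#'   subtree and one metaterm); must not exceed `branching`.
#' @param tree_depth levels in each toy subtree (1 = roots only).
#' @param branching children per internal node, and the number of top-level
#'   specialty subtree roots.
#' @param mixture `NULL` (drawn per cell), a single probability vector over
#'   specialties recycled to every cell, or a matrix with one row per
#'   journal-year cell (journal-major order, years nested).
#' @param headings_per_article length-2 integer range (min, max).
#' @param major_fraction probability that a heading is major (and thus drawn
#'   from the article's specialty subtree rather than the noise subtree).
#' @param overlap_links add extra cross-specialty links so some descriptors
#'   induce two metaterms (exercises multi-metaterm induction; analytic
#'   weight expectations are unavailable in this mode).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             journals = c("BMJ", "JAMA", "Lancet", "NEJM"),
                             years = c(1997L, 2002L, 2007L),
                             n_articles_per_cell = 1174L,
                             n_specialties = 6L,
                             tree_depth = 3L,
                             branching = 6L,
                             mixture = NULL,
                             headings_per_article = c(8L, 12L),
                             major_fraction = 0.157,
                             overlap_links = FALSE) {
  stopifnot(length(journals) >= 1, length(years) >= 1,
            n_articles_per_cell >= 1, n_specialties >= 1,
            tree_depth >= 1, branching >= 1,
            length(headings_per_article) == 2,
            headings_per_article[1] >= 1,
            headings_per_article[2] >= headings_per_article[1],
            major_fraction > 0, major_fraction <= 1)
  if (n_specialties > branching) {
    stop(sprintf("infeasible shape: %d specialties but only %d subtree roots",
                 n_specialties, branching), call. = FALSE)
  }
  n_cells <- length(journals) * length(years)
  if (is.null(mixture)) {
    rng <- local({
      set.seed(as.integer(seed))
      g <- matrix(rexp(n_cells * n_specialties), nrow = n_cells)
      g / rowSums(g)  # flat Dirichlet
    })
    mixture <- rng
  } else if (is.null(dim(mixture))) {
    mixture <- matrix(rep(mixture, each = n_cells), nrow = n_cells)
  }
  mixture <- as.matrix(mixture)
  if (nrow(mixture) != n_cells || ncol(mixture) != n_specialties) {
    stop(sprintf("mixture must be %d cells x %d specialties", n_cells,
                 n_specialties), call. = FALSE)
  }
  if (any(abs(rowSums(mixture) - 1) > 1e-9) || any(mixture < 0)) {
    stop("each mixture vector must be non-negative and sum to 1", call. = FALSE)
  }
  sp <- if (n_specialties <= length(specialty_name_pool)) {
    specialty_name_pool[seq_len(n_specialties)]
  } else {
    c(specialty_name_pool,
      sprintf("specialty %02d",
              seq_len(n_specialties - length(specialty_name_pool))))
  }
  structure(list(seed = as.integer(seed), journals = journals,
                 years = as.integer(years),
                 n_articles_per_cell = as.integer(n_articles_per_cell),
                 n_specialties = as.integer(n_specialties),
                 specialties = sp,
                 tree_depth = as.integer(tree_depth),
                 branching = as.integer(branching),
                 mixture = mixture,
                 headings_per_article = as.integer(headings_per_article),
                 major_fraction = major_fraction,
                 overlap_links = isTRUE(overlap_links)),
            class = "generator_config")
}

# all tree numbers of a complete subtree rooted at `root`, depth levels,
# `branching` children per node, in breadth-first order
subtree_codes <- function(root, depth, branching) {
  levels <- list(root)
  for (d in seq_len(depth - 1L)) {
    prev <- levels[[d]]
    levels[[d + 1L]] <- paste0(rep(prev, each = branching), ".",
                               sprintf("%03d", seq_len(branching)))
  }
  unlist(levels, use.names = FALSE)
}

#' Load the curated MeSH/metaterm fixture
#'
#' The small hand-checked extract shipped with the package: the limb chain
#' Body Regions > ... > Thumb under an anatomy-linked root, Alcoholism under
#' both a toxicology-linked chemically-induced-disorders tree and a
#' psychiatry-linked mental-disorders tree, the two directly-linked
#' psychiatry descriptors, an excluded "statistics" metaterm, and one
#' synthetic qualifier link (therapy -> therapeutics; the qualifier route is
#' unattested upstream). `truth` hand-codes the expected descriptor ->
#' metaterm closure for oracle tests.
#'
#' @return List with `thesaurus`, `links`, and `truth` (tibble
#'   `descriptor_id`, `descriptor_name`, `metaterm`).
#' @export
curated_fixture <- function() {
  thesaurus <- read_thesaurus(system.file("extdata", "mesh_curated.tsv",
                                          package = "meshprofiler"))
  links <- read_link_table(system.file("extdata",
                                       "metaterm_links_curated.tsv",
                                       package = "meshprofiler"))
  truth <- tibble::tribble(
    ~descriptor_id, ~metaterm,
    "D001", "anatomy", "D002", "anatomy", "D003", "anatomy",
    "D004", "anatomy", "D005", "anatomy",
    "D006", "toxicology",
    "D007", "toxicology", "D007", "psychiatry",
    "D008", "toxicology", "D008", "psychiatry",
    "D009", "psychiatry", "D010", "psychiatry", "D011", "psychiatry",
    "D012", "statistics"
  )
  d <- thesaurus$descriptors
  truth$descriptor_name <- d$name[match(truth$descriptor_id, d$id)]
  truth <- dplyr::arrange(truth[c("descriptor_id", "descriptor_name",
                                  "metaterm")],
                          .data$descriptor_id, .data$metaterm)
  list(thesaurus = thesaurus, links = links, truth = truth)
}

#' Generate a toy thesaurus with planted specialty structure
#'
#' Builds `branching` complete subtrees of the requested depth; the root of
#' subtree i (i <= n_specialties) carries the semantic link of specialty i's
#' metaterm, so every descriptor in that subtree induces exactly that
#' metaterm. A separate, never-linked noise subtree (root `Z01`) supplies
#' non-major background headings. The curated fixture is merged in
#' regardless of configuration. The returned `truth` table records the full
#' expected descriptor-to-metaterm closure for oracle tests, and
#' `specialty_descriptors` maps each specialty to the descriptor names of
#' its subtree (the corpus generator's sampling pools).
#'
#' @param config a [generator_config()].
#' @return List with `thesaurus`, `links`, `truth`,
#'   `specialty_descriptors` (named list), and `noise_descriptors`.
#' @export
generate_toy_thesaurus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cur <- curated_fixture()

  roots <- sprintf("S%02d", seq_len(config$branching))
  codes_by_root <- lapply(roots, subtree_codes, depth = config$tree_depth,
                          branching = config$branching)
  noise_codes <- subtree_codes("Z01", config$tree_depth, config$branching)

  all_codes <- c(unlist(codes_by_root, use.names = FALSE), noise_codes)
  toy_desc <- tibble::tibble(
    id = paste0("N", gsub(".", "", all_codes, fixed = TRUE)),
    name = paste("Concept", all_codes),
    tree_numbers = as.list(all_codes)
  )
  descriptors <- dplyr::bind_rows(cur$thesaurus$descriptors, toy_desc)
  thesaurus <- mesh_thesaurus(descriptors, cur$thesaurus$qualifiers)

  sp <- config$specialties
  root_ids <- paste0("N", gsub(".", "", roots, fixed = TRUE))
  toy_links <- tibble::tibble(metaterm = sp,
                              target_id = root_ids[seq_along(sp)],
                              target_kind = "descriptor")
  if (config$overlap_links && length(sp) >= 2) {
    # second specialty's subtree also induces the first metaterm
    toy_links <- dplyr::bind_rows(
      toy_links,
      tibble::tibble(metaterm = sp[1], target_id = root_ids[2],
                     target_kind = "descriptor"))
  }
  links <- metaterm_links(dplyr::bind_rows(cur$links$links, toy_links),
                          cur$links$excluded_metaterms)

  truth_toy <- lapply(seq_along(sp), function(i) {
    codes <- codes_by_root[[i]]
    tt <- tibble::tibble(
      descriptor_id = paste0("N", gsub(".", "", codes, fixed = TRUE)),
      metaterm = sp[i])
    if (config$overlap_links && i == 2) {
      tt <- dplyr::bind_rows(tt,
        tibble::tibble(descriptor_id = tt$descriptor_id, metaterm = sp[1]))
    }
    tt
  })
  truth <- dplyr::bind_rows(cur$truth[c("descriptor_id", "metaterm")],
                            dplyr::bind_rows(truth_toy))
  d <- thesaurus$descriptors
  truth$descriptor_name <- d$name[match(truth$descriptor_id, d$id)]
  truth <- dplyr::arrange(truth[c("descriptor_id", "descriptor_name",
                                  "metaterm")],
                          .data$descriptor_id, .data$metaterm)

  specialty_descriptors <- setNames(
    lapply(seq_along(sp), function(i) paste("Concept", codes_by_root[[i]])),
    sp)
  list(thesaurus = thesaurus, links = links, truth = truth,
       specialty_descriptors = specialty_descriptors,
       noise_descriptors = paste("Concept", noise_codes))
}

#' Generate a synthetic journal corpus with known specialty structure
#'
#' For each journal-year cell, draws `n_articles_per_cell` articles. Each
#' article first draws its specialty from the cell's mixture; each of its
#' headings is then major with probability `major_fraction` — major
#' headings are sampled (with replacement) from the specialty's subtree,
#' the rest from the unlinked noise subtree. Because noise descriptors
#' link to nothing and specialty subtrees are disjoint, an article induces
#' exactly its planted specialty metaterm when it has at least one major
#' heading, which keeps profile-weight expectations closed-form (see
#' [expected_weights()]).
#'
#' @param config a [generator_config()].
#' @param toy result of [generate_toy_thesaurus()] for the same config.
#' @return A [medline_corpus()]. Attributes `specialty` (planted specialty
#'   per article, in article order) and `n_major_planted` (total major
#'   headings drawn) support generator-bookkeeping oracles.
#' @export
generate_corpus <- function(config, toy) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cells <- expand.grid(year = config$years, journal = config$journals,
                       stringsAsFactors = FALSE)[c("journal", "year")]
  # journal-major order, years nested, matching the mixture rows
  cells <- cells[order(match(cells$journal, config$journals), cells$year), ]
  n_cells <- nrow(cells)
  n_art <- n_cells * config$n_articles_per_cell

  cell_of <- rep(seq_len(n_cells), each = config$n_articles_per_cell)
  specialty_idx <- integer(n_art)
  for (c_i in seq_len(n_cells)) {
    sel <- cell_of == c_i
    specialty_idx[sel] <- sample.int(config$n_specialties, sum(sel),
                                     replace = TRUE,
                                     prob = config$mixture[c_i, ])
  }
  hr <- config$headings_per_article
  n_head <- sample(seq(hr[1], hr[2]), n_art, replace = TRUE)
  art_of_head <- rep(seq_len(n_art), times = n_head)
  is_major <- runif(length(art_of_head)) < config$major_fraction

  pools <- toy$specialty_descriptors
  pool_sizes <- lengths(pools)
  desc <- character(length(art_of_head))
  # noise headings
  n_noise <- sum(!is_major)
  desc[!is_major] <- sample(toy$noise_descriptors, n_noise, replace = TRUE)
  # major headings, per specialty pool
  maj_sp <- specialty_idx[art_of_head[is_major]]
  for (s in unique(maj_sp)) {
    sel <- which(is_major)[maj_sp == s]
    desc[sel] <- sample(pools[[s]], length(sel), replace = TRUE)
  }

  ids <- sprintf("%08d", seq_len(n_art))
  articles <- tibble::tibble(article_id = ids,
                             journal = cells$journal[cell_of],
                             year = as.integer(cells$year[cell_of]))
  headings <- tibble::tibble(article_id = ids[art_of_head],
                             descriptor = desc,
                             qualifier = NA_character_,
                             descriptor_major = is_major,
                             qualifier_major = FALSE)
  corpus <- medline_corpus(articles, headings,
                           provenance = sprintf("synthetic (seed %d)",
                                                config$seed))
  attr(corpus, "specialty") <- config$specialties[specialty_idx]
  attr(corpus, "n_major_planted") <- sum(is_major)
  corpus
}

#' Analytic expectation of profiler weights under the generator
#'
#' With disjoint specialty subtrees and unlinked noise headings, an article
#' contributes exactly one metaterm occurrence (its planted specialty) when
#' it has at least one major heading, and none otherwise. Under article-unit
#' counting with the occurrence denominator, the expected relative weight of
#' specialty s in a cell is therefore exactly 100 x mixture[s] — the
#' thinning by articles without major headings cancels between numerator and
#' denominator.
#'
#' @param config a [generator_config()]; must not have `overlap_links` set.
#' @return Tibble with columns `journal`, `year`, `metaterm`,
#'   `expected_weight` (percent).
#' @export
expected_weights <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$overlap_links) {
    stop("expected weights are only available for the non-overlapping link design",
         call. = FALSE)
  }
  cells <- expand.grid(year = config$years, journal = config$journals,
                       stringsAsFactors = FALSE)[c("journal", "year")]
  cells <- cells[order(match(cells$journal, config$journals), cells$year), ]
  tibble::tibble(
    journal = rep(cells$journal, each = config$n_specialties),
    year = as.integer(rep(cells$year, each = config$n_specialties)),
    metaterm = rep(config$specialties, times = nrow(cells)),
    expected_weight = as.vector(t(config$mixture)) * 100
  )
}

#' The published 1997/2002/2007 specialty weights of four journals
#'
#' The printed relative weights (percent) of the fifteen leading specialties
#' in the BMJ, JAMA, Lancet and NEJM for 1997, 2002 and 2007, with the
#' printed 1997-to-2007 integer trend. `self_consistent` flags rows where
#' the printed trend equals [trend_percent()] recomputed from the printed
#' weights (a handful of printed cells disagree with their own weights, most
#' visibly in the JAMA 1997 column).
#'
#' @return Tibble with columns `journal`, `specialty`, `weight_1997`,
#'   `weight_2002`, `weight_2007`, `printed_trend`, `self_consistent`.
#' @export
journal_trend_weights <- function() {
  path <- system.file("extdata", "journal_trend_weights.tsv",
                      package = "meshprofiler")
  tibble::as_tibble(utils::read.delim(path, sep = "\t", quote = "",
                                      stringsAsFactors = FALSE,
                                      encoding = "UTF-8"))
}
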