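#' Construct a MeSH thesaurus object
#'
#' A thesaurus holds MeSH descriptors (each with one or more dot-separated
#' tree numbers encoding hierarchy positions) and qualifiers (subheadings,
#' which carry no hierarchy in this model). An index from tree number to
#' descriptor id supports ancestor queries.
#'
#' @param descriptors tibble with columns `id`, `name`, `tree_numbers`
#'   (list-column of character vectors, each non-empty).
#' @param qualifiers tibble with columns `id`, `name` (may have zero rows).
#' @return An object of class `mesh_thesaurus`.
#' @export
mesh_thesaurus <- function(descriptors, qualifiers = NULL) {
  descriptors <- tibble::as_tibble(descriptors)
  stopifnot(all(c("id", "name", "tree_numbers") %in% names(descriptors)))
  if (is.null(qualifiers)) {
    qualifiers <- tibble::tibble(id = character(), name = character())
  }
  qualifiers <- tibble::as_tibble(qualifiers)

  if (anyDuplicated(descriptors$id)) {
    stop("duplicate descriptor id(s): ",
         paste(unique(descriptors$id[duplicated(descriptors$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(descriptors$name)) {
    stop("duplicate descriptor name(s): ",
         paste(unique(descriptors$name[duplicated(descriptors$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(qualifiers) > 0 && anyDuplicated(qualifiers$id)) {
    stop("duplicate qualifier id(s)", call. = FALSE)
  }
  n_tn <- vapply(descriptors$tree_numbers, length, integer(1))
  if (nrow(descriptors) > 0 && any(n_tn == 0)) {
    stop("descriptor(s) without tree numbers: ",
         paste(descriptors$id[n_tn == 0], collapse = ", "), call. = FALSE)
  }

  tree_index <- tibble::tibble(
    tree_number = unlist(descriptors$tree_numbers, use.names = FALSE),
    id = rep(descriptors$id, times = n_tn)
  )
  if (anyDuplicated(tree_index$tree_number)) {
    dup <- unique(tree_index$tree_number[duplicated(tree_index$tree_number)])
    stop("tree number(s) assigned to more than one descriptor: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  structure(
    list(descriptors = descriptors, qualifiers = qualifiers,
         tree_index = tree_index),
    class = "mesh_thesaurus"
  )
}

#' @export
print.mesh_thesaurus <- function(x, ...) {
  cat(sprintf("<mesh_thesaurus> %d descriptors (%d tree positions), %d qualifiers\n",
              nrow(x$descriptors), nrow(x$tree_index), nrow(x$qualifiers)))
  invisible(x)
}

#' Read a thesaurus from the tabular dialect
#'
#' The canonical fixture format is UTF-8 tab-separated with a header row
#' `id<TAB>name<TAB>tree_numbers`; tree numbers are semicolon-separated.
#' Qualifiers are rows whose `tree_numbers` field is empty.
#'
#' @param path path to the file.
#' @return A [mesh_thesaurus()].
#' @export
read_thesaurus <- function(path) {
  if (!file.exists(path)) stop("thesaurus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]],
                                       c("id", "name", "tree_numbers"))) {
    stop("thesaurus file must start with header 'id\\tname\\ttree_numbers': ",
         path, call. = FALSE)
  }
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 3)) {
    bad <- which(nf < 2 | nf > 3)[1]
    stop(sprintf("malformed thesaurus row at line %d: %s", bad + 1L, body[bad]),
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1)
  names_ <- vapply(parts, `[[`, "", 2)
  tn_raw <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else "", "")
  is_desc <- nzchar(tn_raw)

  descriptors <- tibble::tibble(
    id = ids[is_desc], name = names_[is_desc],
    tree_numbers = strsplit(tn_raw[is_desc], ";", fixed = TRUE)
  )
  qualifiers <- tibble::tibble(id = ids[!is_desc], name = names_[!is_desc])
  mesh_thesaurus(descriptors, qualifiers)
}

#' Write a thesaurus in the tabular dialect
#'
#' Inverse of [read_thesaurus()]; round-trips exactly.
#'
#' @param thesaurus a [mesh_thesaurus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  stopifnot(inherits(thesaurus, "mesh_thesaurus"))
  d <- thesaurus$descriptors
  q <- thesaurus$qualifiers
  rows <- c(
    "id\tname\ttree_numbers",
    sprintf("%s\t%s\t%s", d$id, d$name,
            vapply(d$tree_numbers, paste, "", collapse = ";")),
    if (nrow(q) > 0) sprintf("%s\t%s\t", q$id, q$name)
  )
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

# proper dot-prefixes of one tree number: "A01.378.800" -> c("A01", "A01.378")
tree_prefixes <- function(tree_number) {
  segs <- strsplit(tree_number, ".", fixed = TRUE)[[1]]
  if (length(segs) <= 1) return(character())
  vapply(seq_len(length(segs) - 1L),
         function(k) paste(segs[seq_len(k)], collapse = "."), "")
}

#' Ancestors of a descriptor in the MeSH hierarchy
#'
#' Ancestry is defined by tree-number prefixes: descriptor `e` is an ancestor
#' of `d` if some tree number of `d` strictly extends a tree number of `e`
#' segment-wise. The union is taken over all tree numbers of `d`; the
#' descriptor itself is never returned. Positions whose prefix has no
#' descriptor in the thesaurus are skipped (real MeSH trees are complete, toy
#' trees need not be).
#'
#' @param descriptor a descriptor id or name present in `thesaurus`.
#' @param thesaurus a [mesh_thesaurus()].
#' @return Character vector of ancestor descriptor ids (sorted, unique).
#' @export
mesh_ancestors <- function(descriptor, thesaurus) {
  stopifnot(inherits(thesaurus, "mesh_thesaurus"))
  d <- thesaurus$descriptors
  i <- match(descriptor, d$id)
  if (is.na(i)) i <- match(descriptor, d$name)
  if (is.na(i)) stop("descriptor not in thesaurus: ", descriptor, call. = FALSE)
  prefixes <- unique(unlist(lapply(d$tree_numbers[[i]], tree_prefixes)))
  ids <- thesaurus$tree_index$id[thesaurus$tree_index$tree_number %in% prefixes]
  sort(unique(setdiff(ids, d$id[i])))
}

#' Construct a metaterm semantic-link table
#'
#' A metaterm ("super-concept") names a medical specialty or biological
#' science; each is tied to one or more MeSH descriptors or qualifiers by a
#' manual semantic link. Metaterm names are case-insensitive and stored
#' lower-case. Metaterms flagged excluded (methods / laboratory-test
#' specialties such as "statistics") stay in the table for diagnostics but
#' are dropped from rankings.
#'
#' @param links tibble with columns `metaterm`, `target_id`,
#'   `target_kind` (`"descriptor"` or `"qualifier"`).
#' @param excluded_metaterms character vector of metaterm names to exclude;
#'   must all appear in `links`.
#' @return An object of class `metaterm_links`.
#' @export
metaterm_links <- function(links, excluded_metaterms = character()) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("metaterm", "target_id", "target_kind") %in% names(links)))
  if (!all(links$target_kind %in% c("descriptor", "qualifier"))) {
    stop("target_kind must be 'descriptor' or 'qualifier'", call. = FALSE)
  }
  links$metaterm <- tolower(links$metaterm)
  links <- dplyr::distinct(links, .data$metaterm, .data$target_id,
                           .data$target_kind)
  excluded_metaterms <- tolower(excluded_metaterms)
  unknown <- setdiff(excluded_metaterms, links$metaterm)
  if (length(unknown) > 0) {
    stop("excluded metaterm(s) not present in link table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(links = links,
                 excluded_metaterms = sort(unique(excluded_metaterms))),
            class = "metaterm_links")
}

#' @export
print.metaterm_links <- function(x, ...) {
  cat(sprintf("<metaterm_links> %d links, %d metaterms (%d excluded)\n",
              nrow(x$links), length(unique(x$links$metaterm)),
              length(x$excluded_metaterms)))
  invisible(x)
}

#' Read a metaterm link table
#'
#' Tab-separated with header `metaterm<TAB>target_id<TAB>target_kind<TAB>excluded`,
#' `excluded` being 0 or 1 (a metaterm is excluded if any of its rows says 1).
#'
#' @param path path to the file.
#' @return A [metaterm_links()] object.
#' @export
read_link_table <- function(path) {
  if (!file.exists(path)) stop("link table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("metaterm", "target_id", "target_kind", "excluded")
  if (!all(need %in% names(tab))) {
    stop("link table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  excl <- unique(tolower(tab$metaterm[tab$excluded == 1]))
  metaterm_links(tab[c("metaterm", "target_id", "target_kind")], excl)
}

#' Write a metaterm link table
#'
#' @param links a [metaterm_links()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_link_table <- function(links, path) {
  stopifnot(inherits(links, "metaterm_links"))
  tab <- links$links
  rows <- c("metaterm\ttarget_id\ttarget_kind\texcluded",
            sprintf("%s\t%s\t%s\t%d", tab$metaterm, tab$target_id,
                    tab$target_kind,
                    as.integer(tab$metaterm %in% links$excluded_metaterms)))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Metaterms directly linked to a MeSH target
#'
#' Direct links only — no hierarchy closure (see [induce_for_heading()] for
#' the closed form). Unlinked targets are legal and yield an empty set.
#'
#' @param target_id descriptor or qualifier id.
#' @param kind `"descriptor"` or `"qualifier"`.
#' @param links a [metaterm_links()] object.
#' @return Character vector of metaterm names (sorted, possibly empty).
#' @export
linked_metaterms <- function(target_id, kind = c("descriptor", "qualifier"),
                             links) {
  kind <- match.arg(kind)
  stopifnot(inherits(links, "metaterm_links"))
  tab <- links$links
  sort(unique(tab$metaterm[tab$target_id == target_id &
                             tab$target_kind == kind]))
}
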