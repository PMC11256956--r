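#' Gene set collections
#'
#' A collection of named gene sets, each tagged with a category
#' (pathway / process / regulon / operon / custom), optionally evaluated
#' against a universe of measured genes. Collections are the reference
#' against which bottleneck-node signatures are tested for enrichment.
#'
#' @param sets named list of character vectors (gene IDs). Duplicate IDs
#'   within a set are dropped.
#' @param category optional character vector of categories, named by set or
#'   given in set order; defaults to `"custom"`.
#' @param universe optional character vector of measured gene IDs.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = NULL, universe = NULL) {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("sets must be a named list with unique names")
  if (is.null(names(sets))) names(sets) <- character(0)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  if (is.null(category)) {
    category <- stats::setNames(rep("custom", length(sets)), names(sets))
  } else {
    if (is.null(names(category)))
      category <- stats::setNames(rep_len(category, length(sets)), names(sets))
    category <- category[names(sets)]
    category[is.na(category)] <- "custom"
    names(category) <- names(sets)
  }
  structure(list(sets = sets, category = category,
                 universe = if (!is.null(universe)) unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets),
              if (length(x$sets)) min(lengths(x$sets)) else 0L,
              if (length(x$sets)) max(lengths(x$sets)) else 0L,
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT file
#'
#' Parses the Broad GMT dialect: one set per line,
#' `name TAB description TAB gene TAB gene ...`. Duplicate genes within a
#' line are dropped. Categories can be supplied through a sidecar TSV
#' (`set name TAB category`, no header required) or a single default.
#'
#' @param path GMT file path.
#' @param category default category for sets absent from the sidecar.
#' @param category_path optional sidecar TSV mapping set names to categories.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "custom", category_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  cats <- stats::setNames(rep(category, length(sets)), nm)
  if (!is.null(category_path)) {
    sc <- utils::read.delim(category_path, header = FALSE,
                            stringsAsFactors = FALSE)
    hit <- intersect(nm, sc[[1]])
    cats[hit] <- sc[[2]][match(hit, sc[[1]])]
  }
  gene_set_collection(sets, cats)
}

#' Write a collection to GMT
#'
#' @param coll a [gene_set_collection()].
#' @param path output file.
#' @param description description field written for every set (second GMT
#'   column); defaults to the set's category.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, description = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  desc <- if (is.null(description)) coll$category else
    rep_len(description, length(coll$sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(coll$sets), desc, coll$sets)
  writeLines(unname(lines), path)
  invisible(path)
}

effective_sets <- function(coll) {
  if (is.null(coll$universe)) coll$sets
  else lapply(coll$sets, intersect, coll$universe)
}

#' Filter gene sets by size
#'
#' Retains the sets whose size is at most `max_size`. When the collection
#' carries a universe, size is counted after intersecting each set with the
#' universe, since enrichment statistics are only defined over measured
#' genes. The default 40-gene cap keeps broad catch-all categories out
#' of the tests.
#'
#' @param coll a [gene_set_collection()].
#' @param max_size maximum number of (in-universe) genes, inclusive.
#' @return The filtered collection, original order preserved.
#' @export
filter_by_size <- function(coll, max_size = 40L) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (max_size < 1L) stop("max_size must be >= 1")
  sz <- lengths(effective_sets(coll))
  keep <- sz <= max_size
  gene_set_collection(coll$sets[keep], coll$category[keep], coll$universe)
}

#' Restrict a collection to a gene universe
#'
#' Intersects every set with `gene_ids`, drops sets that become empty, and
#' records `gene_ids` as the collection's universe.
#'
#' @param coll a [gene_set_collection()].
#' @param gene_ids character vector of measured gene IDs.
#' @return The restricted collection.
#' @export
restrict_to_universe <- function(coll, gene_ids) {
  stopifnot(inherits(coll, "gene_set_collection"))
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stop("gene_ids must be non-empty")
  sets <- lapply(coll$sets, intersect, gene_ids)
  keep <- lengths(sets) > 0L
  gene_set_collection(sets[keep], coll$category[keep], gene_ids)
}
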