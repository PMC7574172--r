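# netio: data model for genes, interactomes, gene sets and dated annotations,
# plus readers/writers for the plain-text exchange formats and ID mapping.

#' Construct an interactome
#'
#' An interactome is an undirected, weighted gene association network: a gene
#' universe plus a set of unordered gene pairs, each carrying a weight in
#' \[0, 1\] and a provenance tag (`"known"` experimental interaction or
#' `"predicted"` functional association). Edges are canonicalized with the
#' lexicographically smaller gene first, duplicates are collapsed (a pair seen
#' as both known and predicted stays `known`, and keeps the larger weight),
#' and self-loops are rejected.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (default 1) and `source` (default `"predicted"`).
#' @param genes Optional character vector extending the gene universe beyond
#'   the genes that appear in `edges` (needed wherever all-pairs counts
#'   matter, e.g. size estimation).
#' @return An object of class `interactome`: a list with a `edges` tibble
#'   (`gene_a`, `gene_b`, `weight`, `source`) and a sorted `genes` universe.
#' @examples
#' net <- interactome(data.frame(gene_a = c("g2", "g1"), gene_b = c("g1", "g3")))
#' n_edges(net)
#' @export
interactome <- function(edges = NULL, genes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(gene_a = character(), gene_b = character(),
                            weight = numeric(), source = character())
  } else {
    edges <- tibble::as_tibble(edges)
    stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
    if (!"weight" %in% names(edges)) edges$weight <- 1
    if (!"source" %in% names(edges)) edges$source <- "predicted"
    if (any(edges$gene_a == edges$gene_b)) {
      stop("self-loops are not allowed in an interactome", call. = FALSE)
    }
    if (!all(edges$source %in% c("known", "predicted"))) {
      stop("edge source must be 'known' or 'predicted'", call. = FALSE)
    }
    edges$weight[is.na(edges$weight)] <- 1
    if (any(edges$weight < 0 | edges$weight > 1)) {
      stop("edge weights must lie in [0, 1]", call. = FALSE)
    }
    cp <- canonical_pairs(edges$gene_a, edges$gene_b)
    edges$gene_a <- cp$gene_a
    edges$gene_b <- cp$gene_b
    edges <- edges |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(
        weight = max(.data$weight),
        source = if (any(.data$source == "known")) "known" else "predicted",
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  }
  genes <- sort(unique(c(genes, edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, genes = genes), class = "interactome")
}

#' Number of edges in an interactome
#' @param x An `interactome`.
#' @return Integer edge count.
#' @export
n_edges <- function(x) {
  stopifnot(inherits(x, "interactome"))
  nrow(x$edges)
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", length(x$genes), " genes, ", nrow(x$edges), " edges (",
      sum(x$edges$source == "known"), " known, ",
      sum(x$edges$source == "predicted"), " predicted)\n", sep = "")
  invisible(x)
}

# Named adjacency list (neighbours per gene); genes without edges are absent.
adjacency_list <- function(net) {
  e <- net$edges
  split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = net$genes
  )
}

#' Read an interactome from a tab-separated edge list
#'
#' Expects two or more tab-separated columns per line:
#' `gene_a<TAB>gene_b[<TAB>weight[<TAB>source]]`, no header. A missing weight
#' defaults to 1; a missing source defaults to `source_tag`. Duplicated
#' unordered pairs are collapsed; self-loop lines are skipped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param source_tag Default provenance (`"known"` or `"predicted"`) for lines
#'   without a source column.
#' @param genes Optional explicit gene universe to union into the network.
#' @return An `interactome`.
#' @export
read_edge_list <- function(path, source_tag = "predicted", genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(interactome(genes = genes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2)) {
    stop("malformed edge list line ", which(n_fields < 2)[1],
         ": fewer than 2 tab-separated fields", call. = FALSE)
  }
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  ga <- get_col(1); gb <- get_col(2)
  w_raw <- get_col(3)
  weight <- suppressWarnings(as.numeric(w_raw))
  if (any(!is.na(w_raw) & is.na(weight))) {
    stop("malformed edge list line ", which(!is.na(w_raw) & is.na(weight))[1],
         ": non-numeric weight", call. = FALSE)
  }
  weight[is.na(weight)] <- 1
  src <- get_col(4)
  src[is.na(src)] <- source_tag
  self <- ga == gb
  if (any(self)) {
    warning(sum(self), " self-loop line(s) skipped", call. = FALSE)
  }
  interactome(
    tibble::tibble(gene_a = ga, gene_b = gb, weight = weight,
                   source = src)[!self, ],
    genes = genes
  )
}

#' Write an interactome as a tab-separated edge list
#'
#' Writes the canonical `gene_a<TAB>gene_b<TAB>weight<TAB>source` format read
#' by [read_edge_list()] (no header).
#'
#' @param net An `interactome`.
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  readr::write_tsv(net$edges, path, col_names = FALSE)
  invisible(net)
}

#' Merge two interactomes
#'
#' Edge set is the union of unordered pairs; a pair present in both networks
#' is kept once, tagged `known` if it is known in either, with the larger
#' weight. The gene universe is the union of the two universes.
#'
#' @param a,b `interactome` objects on the same (canonical) ID space.
#' @return Merged `interactome`.
#' @export
merge_interactomes <- function(a, b) {
  stopifnot(inherits(a, "interactome"), inherits(b, "interactome"))
  interactome(dplyr::bind_rows(a$edges, b$edges),
              genes = union(a$genes, b$genes))
}

#' Read a gene set collection from a GMT file
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate members within a line are collapsed. When an ID map is supplied,
#' member genes are mapped first; sets left empty after mapping are dropped
#' with a warning and unmapped IDs are recorded in the `"unmapped"` attribute.
#'
#' @param path Path to a GMT file.
#' @param idmap Optional ID map (see [read_id_map()]).
#' @return A tibble with columns `set_id`, `description` and a `genes`
#'   list-column; attribute `"unmapped"` lists member IDs that could not be
#'   mapped.
#' @export
read_gene_sets <- function(path, idmap = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    stop("GMT line ", which(bad)[1], " has fewer than 3 fields", call. = FALSE)
  }
  set_id <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(set_id)) {
    stop("duplicate set identifiers in GMT: ",
         paste(unique(set_id[duplicated(set_id)]), collapse = ", "),
         call. = FALSE)
  }
  description <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  unmapped <- character()
  if (!is.null(idmap)) {
    members <- lapply(members, function(g) {
      m <- map_ids(g, idmap)
      unmapped <<- union(unmapped, c(m$unmapped, m$ambiguous))
      m$ids
    })
  }
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(set_id[empty], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(set_id = set_id, description = description,
                        genes = members)[!empty, ]
  attr(out, "unmapped") <- unmapped
  out
}

#' Read a dated annotation table
#'
#' Minimal GAF-inspired dialect: `gene<TAB>term<TAB>date`, no header, dates in
#' ISO-8601 (`YYYY-MM-DD`). Duplicate (gene, term) rows are collapsed keeping
#' the earliest date.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene`, `term`, `date` (class `Date`).
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("gene", "term", "date"),
                         col_types = "ccc", progress = FALSE)
  d <- as.Date(tbl$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date in annotation row ", which(is.na(d))[1], ": '",
         tbl$date[which(is.na(d))[1]], "'", call. = FALSE)
  }
  tbl$date <- d
  tbl |>
    dplyr::group_by(.data$gene, .data$term) |>
    dplyr::summarise(date = min(.data$date), .groups = "drop")
}

#' Split an annotation table at a cutoff date
#'
#' Partitions the rows into annotations available at training time
#' (`known`: dated on or before the cutoff) and annotations added later
#' (`new`: dated strictly after the cutoff) — the time-split used to score
#' function prediction on knowledge the network could not have seen.
#'
#' @param annotations Tibble with columns `gene`, `term`, `date`.
#' @param cutoff_date A `Date` (or ISO-8601 string).
#' @return List with elements `known` and `new`, together partitioning the
#'   input rows exactly.
#' @export
split_annotations_by_date <- function(annotations, cutoff_date) {
  stopifnot(all(c("gene", "term", "date") %in% names(annotations)))
  cutoff <- as.Date(cutoff_date)
  if (is.na(cutoff)) stop("unparseable cutoff date", call. = FALSE)
  d <- as.Date(annotations$date)
  if (anyNA(d)) {
    stop("unparseable date in annotation row ", which(is.na(d))[1],
         call. = FALSE)
  }
  list(
    known = annotations[d <= cutoff, , drop = FALSE],
    new   = annotations[d > cutoff, , drop = FALSE]
  )
}

#' Read a two-column ID map
#'
#' @param path TSV with two columns: `source_id<TAB>canonical_id`, no header.
#' @return Tibble with columns `source_id`, `canonical_id`.
#' @export
read_id_map <- function(path) {
  readr::read_tsv(path, col_names = c("source_id", "canonical_id"),
                  col_types = "cc", progress = FALSE) |>
    dplyr::distinct()
}

#' Map identifiers to a canonical ID space
#'
#' Each input ID present in the map is replaced by its canonical ID. IDs that
#' are absent from the map, or that map to more than one canonical target,
#' are excluded from the result and reported — never guessed and never
#' silently dropped.
#'
#' @param ids Character vector of identifiers.
#' @param idmap Tibble with columns `source_id`, `canonical_id`
#'   (see [read_id_map()]).
#' @return List with `ids` (mapped, input order, exclusions removed),
#'   `unmapped` and `ambiguous` character vectors.
#' @export
map_ids <- function(ids, idmap) {
  stopifnot(all(c("source_id", "canonical_id") %in% names(idmap)))
  idmap <- dplyr::distinct(idmap, .data$source_id, .data$canonical_id)
  n_targets <- table(idmap$source_id)
  ambiguous_src <- names(n_targets)[n_targets > 1]
  lut <- setNames(idmap$canonical_id, idmap$source_id)
  is_amb <- ids %in% ambiguous_src
  is_unmapped <- !(ids %in% idmap$source_id)
  keep <- !is_amb & !is_unmapped
  list(
    ids = unname(lut[ids[keep]]),
    unmapped = unique(ids[is_unmapped]),
    ambiguous = unique(ids[is_amb])
  )
}
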