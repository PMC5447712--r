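# Readers and writers for state matrices, variant tables, epigenome
# cluster definitions and CSP catalogs. All coordinates are 0-based
# half-open (BED convention); a position p falls in the window with
# start <= p < end.

#' Construct a validated StateMatrix
#'
#' @param states L x N integer matrix of chromatin-state labels in
#'   \code{1..n_states}; one column per epigenome, one row per window.
#' @param windows data frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open). Generated from a single chromosome
#'   of contiguous windows if omitted.
#' @param epigenome_ids column identifiers (defaults to colnames).
#' @param n_states number of states S (defaults to the observed max).
#' @param window_size window width in bp.
#' @return object of class \code{StateMatrix}.
#' @export
state_matrix <- function(states, windows = NULL, epigenome_ids = NULL,
                         n_states = max(states), window_size = 200L) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (anyNA(states)) stop("state matrix contains missing values")
  if (any(states < 1L) || any(states > n_states))
    stop("state labels must lie in [1, ", n_states, "]")
  L <- nrow(states); N <- ncol(states)
  if (is.null(epigenome_ids))
    epigenome_ids <- colnames(states)
  if (is.null(epigenome_ids))
    epigenome_ids <- paste0("E", seq_len(N))
  if (length(epigenome_ids) != N)
    stop("epigenome_ids must name every column")
  if (is.null(windows)) {
    windows <- data.frame(chrom = "chr1",
                          start = (seq_len(L) - 1L) * window_size,
                          end = seq_len(L) * window_size)
  }
  stopifnot(nrow(windows) == L,
            all(c("chrom", "start", "end") %in% names(windows)))
  if (any(windows$end - windows$start != window_size))
    stop("every window must span exactly window_size bp")
  if (any(windows$start < 0)) stop("window starts must be >= 0")
  for (ch in unique(windows$chrom)) {
    s <- windows$start[windows$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      stop("windows must be sorted and non-overlapping per chromosome")
  }
  colnames(states) <- epigenome_ids
  structure(list(epigenome_ids = epigenome_ids,
                 windows = windows[, c("chrom", "start", "end")],
                 states = states, n_states = as.integer(n_states),
                 window_size = as.integer(window_size)),
            class = "StateMatrix")
}

#' @export
print.StateMatrix <- function(x, ...) {
  cat(sprintf(
    "StateMatrix: %d windows x %d epigenomes, %d states, %d bp windows\n",
    nrow(x$states), ncol(x$states), x$n_states, x$window_size))
  invisible(x)
}

#' Read a chromatin-state matrix
#'
#' Expects a tab-delimited file with a header row
#' \code{#chrom start end <epigenome ids...>} and one body row per
#' genomic window: BED-compatible coordinates followed by one integer
#' state label per epigenome.
#'
#' @param path file path.
#' @param n_states number of states S; labels outside \code{[1, S]} are
#'   a validation error naming the offending row.
#' @param window_size expected window width in bp.
#' @return a \code{StateMatrix}.
#' @export
read_state_matrix <- function(path, n_states, window_size = 200L) {
  header <- strsplit(sub("^#", "", readLines(path, n = 1L)), "\t")[[1]]
  if (length(header) < 4L)
    stop("state matrix header must list chrom, start, end and ",
         "at least one epigenome")
  epi <- header[-(1:3)]
  tab <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                           col.names = header, comment.char = "",
                           colClasses = c("character", "integer",
                                          "integer",
                                          rep("integer", length(epi))))
  if (ncol(tab) != length(header))
    stop("ragged row: expected ", length(header), " fields")
  sts <- as.matrix(tab[, -(1:3), drop = FALSE])
  bad <- which(rowSums(sts < 1L | sts > n_states) > 0L)
  if (length(bad) > 0L)
    stop("state label outside [1, ", n_states, "] in data row ", bad[1L])
  state_matrix(sts,
               windows = data.frame(chrom = tab[[1]], start = tab[[2]],
                                    end = tab[[3]]),
               epigenome_ids = epi, n_states = n_states,
               window_size = window_size)
}

#' Write a StateMatrix in the tab-delimited exchange format
#'
#' @param states a \code{StateMatrix}.
#' @param path output file path.
#' @export
write_state_matrix <- function(states, path) {
  header <- paste(c("#chrom", "start", "end", states$epigenome_ids),
                  collapse = "\t")
  body <- cbind(states$windows, as.data.frame(states$states))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map positions to windows
#'
#' @param chrom,pos vectors of variant coordinates (0-based).
#' @param states a \code{StateMatrix}.
#' @return integer vector of window row indices; NA when a position
#'   falls outside every window of its chromosome.
#' @keywords internal
window_index <- function(chrom, pos, states) {
  w <- states$windows
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    rows <- which(w$chrom == ch)
    if (length(rows) == 0L) next
    hit <- findInterval(pos[sel], w$start[rows])
    ok <- hit >= 1L & pos[sel] < w$end[rows][pmax(hit, 1L)]
    idx[sel[ok]] <- rows[hit[ok]]
  }
  idx
}

#' Construct a VariantSet
#'
#' @param variants data frame with columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{ld_cluster}, \code{maf},
#'   \code{annotation}, \code{label} (\code{"risk"} or \code{"null"}).
#' @param states n x N integer matrix: the chromatin states of the
#'   window containing each variant.
#' @return object of class \code{VariantSet}.
#' @export
variant_set <- function(variants, states) {
  need <- c("variant_id", "chrom", "pos", "ld_cluster", "maf",
            "annotation", "label")
  stopifnot(all(need %in% names(variants)))
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) != nrow(variants))
    stop("one state vector per variant required")
  if (any(variants$maf < 0 | variants$maf > 0.5))
    stop("maf must lie in [0, 0.5]")
  if (!all(variants$label %in% c("risk", "null")))
    stop("label must be 'risk' or 'null'")
  structure(list(variants = variants[, need], states = states),
            class = "VariantSet")
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("VariantSet: %d variants (%d risk, %d null), %d epigenomes\n",
              nrow(x$variants), sum(x$variants$label == "risk"),
              sum(x$variants$label == "null"), ncol(x$states)))
  invisible(x)
}

#' Subset a VariantSet
#' @param x a \code{VariantSet}; @param i row indices or logical mask.
#' @param ... unused.
#' @export
`[.VariantSet` <- function(x, i, ...) {
  variant_set(x$variants[i, , drop = FALSE],
              x$states[i, , drop = FALSE])
}

#' Number of variants in a VariantSet
#' @param x a \code{VariantSet}.
#' @export
length.VariantSet <- function(x) nrow(x$variants)

#' Read a variant table and attach per-epigenome states
#'
#' The table is tab-delimited with columns \code{variant_id chrom pos
#' ld_cluster maf annotation label}. Each variant is annotated with the
#' state vector of the window containing its (0-based) position;
#' variants outside every window are dropped with a warning.
#'
#' @param path file path.
#' @param states a \code{StateMatrix} covering the variants.
#' @return a \code{VariantSet}.
#' @export
read_variants <- function(path, states) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "",
                           stringsAsFactors = FALSE)
  names(tab) <- sub("^X\\.", "", names(tab))
  idx <- window_index(tab$chrom, tab$pos, states)
  drop <- is.na(idx)
  if (any(drop))
    warning(sum(drop), " variant(s) outside the covered windows dropped")
  tab <- tab[!drop, , drop = FALSE]
  variant_set(tab, states$states[idx[!drop], , drop = FALSE])
}

#' Write a variant table
#' @param variants a \code{VariantSet}; @param path output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an epigenome cluster definition
#'
#' @param cluster_of named integer vector mapping each epigenome id to a
#'   cluster label in \code{1..G}; the partition must be exhaustive over
#'   the epigenomes it is used with.
#' @return object of class \code{ClusterDefinition} with derived
#'   proportions \code{p_g}.
#' @export
cluster_definition <- function(cluster_of) {
  stopifnot(!is.null(names(cluster_of)), all(cluster_of >= 1L))
  G <- max(cluster_of)
  p_g <- tabulate(cluster_of, nbins = G) / length(cluster_of)
  ci <- as.integer(cluster_of)
  names(ci) <- names(cluster_of)
  structure(list(cluster_of = ci, n_clusters = as.integer(G),
                 p_g = p_g), class = "ClusterDefinition")
}

#' Read an epigenome-cluster definition table
#'
#' Tab-delimited, two columns: \code{epigenome_id} and integer
#' \code{cluster}.
#'
#' @param path file path.
#' @return a \code{ClusterDefinition}.
#' @export
read_clusters <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  cluster_definition(stats::setNames(as.integer(tab$cluster),
                                     tab$epigenome_id))
}

#' Write an epigenome-cluster definition table
#' @param clusters a \code{ClusterDefinition}; @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(
    data.frame(epigenome_id = names(clusters$cluster_of),
               cluster = clusters$cluster_of),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a CSP catalog to a structured text file
#'
#' One header block (capacity, epigenome count, K, the Dirichlet prior)
#' followed by one line per pattern: id, occurrence count, and the
#' group label of every epigenome. \code{read_catalog(write_catalog(x))}
#' is the identity.
#'
#' @param catalog a \code{CSPCatalog}; @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cspattern catalog v1", con)
  writeLines(sprintf("n_patterns\t%d", length(catalog$patterns)), con)
  writeLines(sprintf("n_epigenomes\t%d", length(catalog$patterns[[1]])),
             con)
  writeLines(sprintf("K\t%d", catalog$K), con)
  writeLines(paste(c("alpha", format(catalog$alpha, digits = 17)),
                   collapse = "\t"), con)
  ids <- catalog$epigenome_ids
  if (is.null(ids)) ids <- ""
  writeLines(paste(c("epigenomes", ids), collapse = "\t"), con)
  for (c in seq_along(catalog$patterns)) {
    writeLines(paste(c("pattern", c,
                       format(catalog$counts[c], digits = 17),
                       catalog$patterns[[c]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_catalog
#' @return \code{read_catalog} returns the deserialized
#'   \code{CSPCatalog}.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L || lines[1L] != "# cspattern catalog v1")
    stop("not a cspattern catalog file")
  fld <- strsplit(lines, "\t")
  key <- vapply(fld, `[`, character(1), 1L)
  take <- function(name) {
    i <- match(name, key)
    if (is.na(i)) stop("malformed catalog: missing ", name)
    fld[[i]][-1L]
  }
  n_pat <- as.integer(take("n_patterns"))
  n_epi <- as.integer(take("n_epigenomes"))
  K <- as.integer(take("K"))
  alpha <- as.numeric(take("alpha"))
  ids <- take("epigenomes")
  if (identical(ids, "")) ids <- NULL
  pat_rows <- which(key == "pattern")
  if (length(pat_rows) != n_pat)
    stop("malformed catalog: expected ", n_pat, " patterns, found ",
         length(pat_rows))
  patterns <- vector("list", n_pat)
  counts <- numeric(n_pat)
  for (r in pat_rows) {
    v <- fld[[r]][-1L]
    if (length(v) != n_epi + 2L)
      stop("malformed catalog: truncated pattern line")
    id <- as.integer(v[1L])
    counts[id] <- as.numeric(v[2L])
    patterns[[id]] <- as.integer(v[-(1:2)])
  }
  csp_catalog(patterns, counts = counts, K = K, alpha = alpha,
              epigenome_ids = ids)
}

#' Write a pattern assignment as a BED-like track
#'
#' @param assignment integer pattern indices per window.
#' @param states the \code{StateMatrix} supplying window coordinates.
#' @param path output path.
#' @export
write_assignment <- function(assignment, states, path) {
  utils::write.table(
    cbind(states$windows, pattern = assignment), path, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
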