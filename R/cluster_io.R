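#' Read SPRITE cluster files
#'
#' Parses a text file of SPRITE clusters: one cluster per line, TAB-separated,
#' the first field an opaque cluster identifier and each further field a read
#' token `chrom:position` or `chrom:position:mapq`. Lines beginning with `#`
#' are comments. Reads with a MAPQ below `mapq_min` are removed; reads without
#' a MAPQ field pass unfiltered (deposited cluster files are already
#' alignment-filtered, so a missing field means "pre-filtered"). Clusters
#' emptied by filtering are dropped.
#'
#' @param path Path to the cluster file.
#' @param mapq_min Minimum mapping quality retained; default 30.
#' @param chromosome_filter Optional character vector; when given, reads on
#'   other chromosomes are discarded (clusters emptied this way are dropped).
#'
#' @return A list of `sprite_cluster` objects, each a list with elements
#'   `cluster_id`, `chromosome` (character vector), `position` (integer
#'   vector, 1-based) and `mapq` (integer vector, `NA` where absent).
#' @seealso [bin_cluster()], [write_cluster_file()]
#' @export
read_sprite_clusters <- function(path, mapq_min = 30L, chromosome_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no cluster records in ", path)
    return(list())
  }
  out <- vector("list", length(lines))
  n_out <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("line ", lineno[i], ": cluster record needs an id and at least one read")
    id <- fields[1L]
    toks <- strsplit(fields[-1L], ":", fixed = TRUE)
    np <- lengths(toks)
    if (any(np < 2L | np > 3L))
      stop("line ", lineno[i], ": malformed read token '",
           fields[-1L][which(np < 2L | np > 3L)[1L]], "'")
    chrom <- vapply(toks, `[[`, "", 1L)
    pos_s <- vapply(toks, `[[`, "", 2L)
    if (!all(grepl("^[0-9]+$", pos_s)))
      stop("line ", lineno[i], ": malformed read token '",
           fields[-1L][which(!grepl("^[0-9]+$", pos_s))[1L]], "' (position not an integer)")
    pos <- as.integer(pos_s)
    if (any(pos < 1L))
      stop("line ", lineno[i], ": read position must be >= 1")
    mapq <- rep(NA_integer_, length(toks))
    has_q <- np == 3L
    if (any(has_q)) {
      q_s <- vapply(toks[has_q], `[[`, "", 3L)
      if (!all(grepl("^[0-9]+$", q_s)))
        stop("line ", lineno[i], ": malformed MAPQ in read token")
      mapq[has_q] <- as.integer(q_s)
    }
    sel <- is.na(mapq) | mapq >= mapq_min
    if (!is.null(chromosome_filter)) sel <- sel & chrom %in% chromosome_filter
    if (!any(sel)) next
    n_out <- n_out + 1L
    out[[n_out]] <- structure(
      list(cluster_id = id, chromosome = chrom[sel],
           position = pos[sel], mapq = mapq[sel]),
      class = "sprite_cluster"
    )
  }
  out[seq_len(n_out)]
}

#' Bin a SPRITE cluster into fixed-width genomic bins
#'
#' Reduces one cluster to its set of distinct bins on the target chromosome.
#' Multiple reads in the same bin count once, so the cluster order `k` is the
#' number of distinct bins touched — except that clusters whose reads all fall
#' in a single bin are kept and counted as 2-mers (`single_bin_flag = TRUE`).
#' Reads on other chromosomes are ignored (analyses are intra-chromosomal);
#' a cluster qualifies only if at least two of its reads lie on the target
#' chromosome, so single-read clusters yield `NULL`.
#'
#' @param cluster A `sprite_cluster` from [read_sprite_clusters()].
#' @param binning A [genome_binning()] for the target chromosome.
#'
#' @return A `binned_cluster` (list with `chromosome`, `bins` — strictly
#'   increasing 0-based indices —, `k`, `single_bin_flag`), or `NULL` if fewer
#'   than two reads lie on `binning$chromosome`.
#' @examples
#' b <- genome_binning("chr1", 1e6, 25000)
#' cl <- structure(list(cluster_id = "c", chromosome = rep("chr1", 3),
#'                      position = c(100L, 24999L, 25001L),
#'                      mapq = rep(NA_integer_, 3)), class = "sprite_cluster")
#' bin_cluster(cl, b)$bins   # 0 1
#' @export
bin_cluster <- function(cluster, binning) {
  stopifnot(inherits(cluster, "sprite_cluster"), inherits(binning, "genome_binning"))
  on_chrom <- cluster$chromosome == binning$chromosome
  if (sum(on_chrom) < 2L) return(NULL)
  pos <- cluster$position[on_chrom]
  bad <- pos > binning$chrom_length
  if (any(bad))
    stop("cluster ", cluster$cluster_id, ": read at ", binning$chromosome, ":",
         pos[which(bad)[1L]], " beyond chromosome length ", binning$chrom_length)
  bins <- sort(unique(bin_index(pos, binning)))
  single <- length(bins) == 1L
  structure(
    list(chromosome = binning$chromosome,
         bins = bins,
         k = if (single) 2L else length(bins),
         single_bin_flag = single),
    class = "binned_cluster"
  )
}

#' Bin many clusters at once
#'
#' Convenience wrapper around [bin_cluster()] that drops non-qualifying
#' clusters (fewer than two reads on the target chromosome).
#'
#' @inheritParams bin_cluster
#' @param clusters List of `sprite_cluster` objects.
#' @return List of `binned_cluster` objects.
#' @export
bin_clusters <- function(clusters, binning) {
  out <- lapply(clusters, bin_cluster, binning = binning)
  out[!vapply(out, is.null, TRUE)]
}

#' @export
print.binned_cluster <- function(x, ...) {
  cat(sprintf("<binned_cluster> %s k=%d%s bins: %s\n", x$chromosome, x$k,
              if (x$single_bin_flag) " (single-bin)" else "",
              paste(x$bins, collapse = ",")))
  invisible(x)
}

#' Read a Hi-C triplet ("RAWobserved") file into a contact matrix
#'
#' Reads the standard 3-column sparse dialect: each line gives the genomic
#' start coordinate of bin i, of bin j, and the raw contact count. Coordinates
#' must be multiples of the resolution. Missing pairs are zero; the matrix is
#' symmetrized. Lines beginning with `#` are skipped.
#'
#' @param path Path to the triplet file.
#' @param binning A [genome_binning()].
#' @return A [contact_matrix()] with scheme `"hic-raw"`.
#' @export
read_hic_triplets <- function(path, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  if (!file.exists(path)) stop("file not found: ", path)
  n <- binning$n_bins
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("ci", "cj", "count"),
                      colClasses = c("numeric", "numeric", "numeric")),
    error = function(e) NULL
  )
  M <- matrix(0, n, n)
  if (is.null(dat) || nrow(dat) == 0L) {
    warning("no triplet records in ", path, "; returning all-zero matrix")
    return(contact_matrix(M, binning$chromosome, binning$resolution, "hic-raw"))
  }
  res <- binning$resolution
  if (any(dat$ci %% res != 0 | dat$cj %% res != 0))
    stop("coordinate not a multiple of resolution ", res, " in ", path)
  if (any(dat$count < 0)) stop("negative count in ", path)
  i <- dat$ci / res
  j <- dat$cj / res
  if (any(i >= n | j >= n))
    stop("coordinate beyond chromosome ", binning$chromosome,
         " (", n, " bins) in ", path)
  M[cbind(i + 1, j + 1)] <- dat$count
  M[cbind(j + 1, i + 1)] <- dat$count
  contact_matrix(M, binning$chromosome, binning$resolution, "hic-raw")
}
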