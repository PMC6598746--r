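# Alignments over the 5-state alphabet {A,C,G,T,-} (N = fully ambiguous),
# FASTA / Newick round-trips, and partitioned supermatrices.
#
# Internal coordinates are plain R (1-based) column indices; user-facing
# partition tables are 1-based inclusive ranges, matching the convention of
# partitioned parsimony software.

ALPHABET <- c("A", "C", "G", "T", "-")

#' Construct a locus alignment
#'
#' @param mat character matrix (samples x columns) over `{A,C,G,T,-,N}`;
#'   rownames are sample ids.
#' @param locus_name name of the marker.
#' @param outgroup_id optional sample id to root displayed trees on.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(mat, locus_name, outgroup_id = NULL) {
  stopifnot(is.matrix(mat), is.character(mat), ncol(mat) >= 1)
  ids <- rownames(mat)
  if (is.null(ids)) stop("matrix must carry sample ids as rownames")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- toupper(mat)
  bad <- !(mat %in% c(ALPHABET, "N"))
  if (any(bad)) {
    stop("characters outside {A,C,G,T,-,N}: ",
         paste(unique(mat[bad]), collapse = ", "))
  }
  if (!is.null(outgroup_id) && !outgroup_id %in% ids) {
    stop("outgroup '", outgroup_id, "' not among sample ids")
  }
  structure(list(locus_name = locus_name, sample_ids = ids, matrix = mat,
                 outgroup_id = outgroup_id),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_name, ": ", length(x$sample_ids),
      " samples x ", ncol(x$matrix), " columns\n", sep = "")
  invisible(x)
}

n_samples <- function(aln) length(aln$sample_ids)
n_columns <- function(aln) ncol(aln$matrix)

#' Read a FASTA alignment
#'
#' Records must all have the same length; characters are upper-cased and
#' validated against `{A,C,G,T,-,N}`.
#'
#' @param path FASTA file.
#' @param locus_name marker name to attach.
#' @param outgroup_id optional outgroup sample id.
#' @return a [locus_alignment].
#' @export
read_alignment_fasta <- function(path, locus_name, outgroup_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    off <- ids[lens != lens[1]][1]
    stop("ragged alignment: record '", off, "' has length ",
         lens[lens != lens[1]][1], ", expected ", lens[1])
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  locus_alignment(mat, locus_name, outgroup_id)
}

#' Write an alignment to FASTA
#' @param aln a [locus_alignment].
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  out <- character(2L * n_samples(aln))
  out[c(TRUE, FALSE)] <- paste0(">", aln$sample_ids)
  out[c(FALSE, TRUE)] <- apply(aln$matrix, 1, paste, collapse = "")
  writeLines(out, path)
  invisible(path)
}

#' Encode an alignment on the 5-state alphabet
#'
#' Gaps are a fifth character state. The documented code mapping is
#' A=0, C=1, G=2, T=3, gap=4; `N` becomes the fully ambiguous state
#' (matches any of the five). The returned object also carries the bitmask
#' representation the parsimony engine consumes (bit k set = state k
#' allowed) and a site-pattern compression.
#'
#' @param aln a [locus_alignment].
#' @return object of class `five_state` with elements `codes`
#'   (integer matrix, values 0..4, `NA` where fully ambiguous), `masks`
#'   (integer bitmask matrix), `sample_ids`, and pattern compression
#'   (`pat_masks`, `pat_weights`, `pat_index`).
#' @export
encode_five_state <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  chars <- aln$matrix
  codes <- matrix(match(chars, ALPHABET) - 1L, nrow = nrow(chars))
  masks <- matrix(ifelse(is.na(codes), 31L, bitwShiftL(1L, codes)),
                  nrow = nrow(chars))
  rownames(codes) <- rownames(masks) <- aln$sample_ids
  # site-pattern compression
  key <- apply(masks, 2, paste, collapse = ",")
  pat_index <- match(key, unique(key))
  first <- !duplicated(key)
  pat_masks <- masks[, first, drop = FALSE]
  pat_weights <- as.integer(tabulate(pat_index, nbins = sum(first)))
  structure(list(codes = codes, masks = masks, sample_ids = aln$sample_ids,
                 locus_name = aln$locus_name,
                 pat_masks = pat_masks, pat_weights = pat_weights,
                 pat_index = pat_index),
            class = "five_state")
}

#' Decode a 5-state encoding back to characters
#' @param enc a `five_state` object.
#' @return character matrix over `{A,C,G,T,-,N}`.
#' @export
decode_five_state <- function(enc) {
  stopifnot(inherits(enc, "five_state"))
  out <- matrix(ifelse(is.na(enc$codes), "N", ALPHABET[enc$codes + 1L]),
                nrow = nrow(enc$codes))
  rownames(out) <- enc$sample_ids
  out
}

#' Concatenate locus alignments into a partitioned supermatrix
#'
#' All inputs must share the same sample-id set (exact string match); rows
#' are aligned by id and columns appended in the given order. Partition
#' ranges are recorded as 1-based inclusive coordinates.
#'
#' @param alignments list of [locus_alignment] objects.
#' @return object of class `partitioned_alignment` with elements
#'   `supermatrix` (a [locus_alignment]) and `partitions` (data.frame with
#'   columns locus, start, end).
#' @export
concatenate_partitions <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  ids <- alignments[[1]]$sample_ids
  for (a in alignments[-1]) {
    extra <- setdiff(a$sample_ids, ids)
    miss <- setdiff(ids, a$sample_ids)
    if (length(extra) || length(miss)) {
      stop("sample sets differ between loci '", alignments[[1]]$locus_name,
           "' and '", a$locus_name, "'; only in first: ",
           paste(miss, collapse = ","), "; only in second: ",
           paste(extra, collapse = ","))
    }
  }
  ids <- sort(ids)
  mats <- lapply(alignments, function(a) a$matrix[ids, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  supermat <- do.call(cbind, mats)
  og <- alignments[[1]]$outgroup_id
  structure(list(
    supermatrix = locus_alignment(supermat, "concatenated", og),
    partitions = data.frame(
      locus = vapply(alignments, function(a) a$locus_name, character(1)),
      start = starts, end = ends, stringsAsFactors = FALSE)),
    class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat("<partitioned_alignment> ", length(x$supermatrix$sample_ids),
      " samples x ", ncol(x$supermatrix$matrix), " columns\n", sep = "")
  for (i in seq_len(nrow(x$partitions))) {
    cat(sprintf("  %s = %d-%d\n", x$partitions$locus[i],
                x$partitions$start[i], x$partitions$end[i]))
  }
  invisible(x)
}

#' Extract one partition as a locus alignment
#' @param pa a `partitioned_alignment`.
#' @param locus partition name or index.
#' @export
extract_partition <- function(pa, locus) {
  i <- if (is.character(locus)) match(locus, pa$partitions$locus) else locus
  if (is.na(i) || i < 1 || i > nrow(pa$partitions)) stop("no such partition: ", locus)
  cols <- pa$partitions$start[i]:pa$partitions$end[i]
  locus_alignment(pa$supermatrix$matrix[, cols, drop = FALSE],
                  pa$partitions$locus[i], pa$supermatrix$outgroup_id)
}

#' Write a partition table
#'
#' `format = "text"` writes RAxML-style lines (`locus = start-end`);
#' `format = "json"` writes a JSON array of `{locus, start, end}` records.
#' @param pa a `partitioned_alignment`.
#' @param path output file.
#' @param format "text" or "json".
#' @export
write_partition_table <- function(pa, path, format = c("text", "json")) {
  format <- match.arg(format)
  p <- pa$partitions
  if (format == "text") {
    writeLines(sprintf("%s = %d-%d", p$locus, p$start, p$end), path)
  } else {
    jsonlite::write_json(p, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Attach an outgroup sequence to an alignment
#'
#' The outgroup is one more aligned row; trees are rooted on it for display
#' only (all test statistics are computed on unrooted topologies).
#'
#' @param aln a [locus_alignment].
#' @param sequence character vector (or single string) of the aligned
#'   outgroup sequence, same length as the alignment.
#' @param id outgroup sample id.
#' @export
attach_outgroup <- function(aln, sequence, id) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != n_columns(aln)) {
    stop("outgroup length ", length(sequence), " != alignment columns ",
         n_columns(aln))
  }
  m <- rbind(aln$matrix, toupper(sequence))
  rownames(m) <- c(aln$sample_ids, id)
  locus_alignment(m, aln$locus_name, outgroup_id = id)
}

#' Root a tree on the outgroup for display
#' @param tree a `phylo` containing the outgroup leaf.
#' @param outgroup_id outgroup tip label.
#' @export
root_on_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label) {
    stop("outgroup '", outgroup_id, "' not in tree")
  }
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Read trees from a Newick file
#'
#' Accepts the support-as-internal-node-label dialect and polytomies.
#' @param path Newick file (one or more trees).
#' @return a `multiPhylo` (even for a single tree).
#' @export
read_newick <- function(path) {
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("Newick parse error in '", path,
                                             "': ", conditionMessage(e)))
  if (is.null(trees)) stop("Newick parse error in '", path, "'")
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

#' Write trees to a Newick file
#' @param trees a `phylo` or `multiPhylo`.
#' @param path output file.
#' @export
write_newick <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}
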