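#' Read / write protein FASTA with taxon-tagged headers
#'
#' Headers follow the dialect `>id|taxon`; a header without a pipe gets
#' taxon `"unknown"`. Sequences are uppercased and `'*'` terminators are
#' stripped. The round trip through [write_fasta()] is lossless.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `taxon`, `residues`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(set)
  id <- sub("\\|.*$", "", hdr)
  taxon <- ifelse(grepl("\\|", hdr), sub("^[^|]*\\|", "", hdr), "unknown")
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  data.frame(id = id, taxon = taxon, residues = seqs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param records data.frame with `id`, `taxon`, `residues`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "taxon", "residues") %in% names(records)))
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(records$taxon == "unknown", records$id,
                       paste0(records$id, "|", records$taxon))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Find a PDR signature motif
#'
#' All (possibly overlapping) exact matches of a motif pattern in which `X`
#' matches any single residue and every other letter matches itself.
#'
#' @param seq a protein sequence (single string).
#' @param pattern motif pattern over amino-acid letters plus `X`
#'   (length >= 3).
#' @return integer vector of 1-based start positions (possibly empty).
#' @examples
#' find_motif("AALLAGPPKK", "LLXGPP") # 3
#' @export
find_motif <- function(seq, pattern) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(pattern), length(pattern) == 1L,
            nchar(pattern) >= 3L, grepl("^[A-Z]+$", pattern))
  if (nchar(pattern) > nchar(seq)) return(integer())
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Full-size ABCG filter specification
#'
#' Length bounds and the plant PDR signature motifs that define a full-size
#' ABCG/PDR sequence: length between 950 and 1800 residues (inclusive) and
#' at least one match of each motif `LLXGPP`, `GLXSS`, `GLDARXAAXVMR`,
#' `VCTIHQP` (`X` = any residue).
#'
#' @param min_len,max_len inclusive length bounds (defaults 950, 1800).
#' @param motifs character vector of motif patterns.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(min_len = 950L, max_len = 1800L,
                        motifs = c("LLXGPP", "GLXSS", "GLDARXAAXVMR",
                                   "VCTIHQP")) {
  stopifnot(min_len <= max_len, length(motifs) >= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 motifs = motifs), class = "filter_spec")
}

#' Screen sequences for full-size ABCG membership
#'
#' Keeps a record iff its length lies within the bounds and every motif has
#' at least one match. Rejection reasons name the first failing criterion
#' (`"length"`, then `"motif <pattern>"` in motif order). The filter is
#' idempotent on its own `kept` output, and `kept`/`rejected` partition the
#' input.
#'
#' @param records data.frame as from [read_fasta()].
#' @param spec a [filter_spec()].
#' @return list with `kept` (records subset) and `rejected` (data.frame
#'   `id`, `reason`).
#' @export
filter_full_size <- function(records, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    s <- records$residues[i]
    n <- nchar(s)
    if (n < spec$min_len || n > spec$max_len) return("length")
    for (m in spec$motifs)
      if (length(find_motif(s, m)) == 0L) return(paste("motif", m))
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  list(kept = records[keep, , drop = FALSE],
       rejected = data.frame(id = records$id[!keep],
                             reason = reasons[!keep],
                             stringsAsFactors = FALSE, row.names = NULL))
}

# BLOSUM62 as shipped with Biostrings (the standard NCBI matrix), cached
blosum_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' @return the standard BLOSUM62 integer matrix (rows/columns named by
#'   amino-acid letters, including B, Z, X and `*`).
#' @export
blosum62 <- function() {
  if (is.null(blosum_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$B62 <- e$BLOSUM62
  }
  blosum_env$B62
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch / Gotoh global alignment maximising the substitution
#' score under an affine gap cost in which a gap run of length L costs
#' `gap_open + L * gap_extend` (both negative). Traceback tie-breaking is
#' deterministic: diagonal, then up (gap in `b`), then left (gap in `a`).
#'
#' @param a,b protein sequences (single strings; `a` may be empty only
#'   together with a non-empty `b` and vice versa).
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix with letter dimnames.
#' @param gap_open gap opening penalty (default -10).
#' @param gap_extend per-residue gap extension penalty (default -0.5).
#' @return list with `aligned_a`, `aligned_b` (gap `'-'`) and `score`.
#' @export
align_global <- function(a, b, matrix = "BLOSUM62", gap_open = -10,
                         gap_extend = -0.5) {
  if (is.character(matrix) && length(matrix) == 1L) {
    if (matrix != "BLOSUM62") stop("unknown substitution matrix: ", matrix)
    matrix <- blosum62()
  }
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)),
            identical(colnames(matrix), rownames(matrix)))
  if (nchar(a) == 0L && nchar(b) == 0L)
    return(list(aligned_a = "", aligned_b = "", score = 0))
  cpp_align_global(a, b, matrix, paste(colnames(matrix), collapse = ""),
                   gap_open, gap_extend)
}

#' Extracellular-gate annotation of the AtABCG36 reference
#'
#' The four gate positions (703, 704, 1374, 1375; 1-based on the reference)
#' and the four transmembrane-helix segments whose geometric centre defines
#' the translocation coordinate, with their reference sequences.
#'
#' @return list with `reference_id`, `gate_positions`, `helix_segments`
#'   (data.frame `start`, `end`, `seq`).
#' @export
gate_annotation <- function() {
  seg <- data.frame(
    start = c(582L, 685L, 1250L, 1356L),
    end = c(597L, 700L, 1265L, 1371L),
    seq = c("FGMIINMFNGFAEMAM", "IANTGGALTLLLVFLL",
            "LYAAIIFVGINNCSTV", "VASIFASAFYGIFNLF"),
    stringsAsFactors = FALSE)
  stopifnot(all(nchar(seg$seq) == seg$end - seg$start + 1L))
  list(reference_id = "AtABCG36",
       gate_positions = c(703L, 704L, 1374L, 1375L),
       helix_segments = seg)
}

#' Residue identity at reference positions inside the annotated segments
#'
#' Looks a reference position up in the helix-segment strings of a
#' [gate_annotation()]; errors for positions outside every segment.
#'
#' @param positions integer positions (1-based on the reference).
#' @param annotation a [gate_annotation()].
#' @return named character vector of residues.
#' @examples
#' segment_residue(698) # "F"
#' @export
segment_residue <- function(positions, annotation = gate_annotation()) {
  seg <- annotation$helix_segments
  vapply(positions, function(p) {
    i <- which(seg$start <= p & p <= seg$end)
    if (length(i) != 1L)
      stop("position ", p, " lies outside the annotated segments")
    substr(seg$seq[i], p - seg$start[i] + 1L, p - seg$start[i] + 1L)
  }, character(1)) |> setNames(positions)
}

#' Validate an aligned panel
#'
#' An MSA here is a records data.frame whose `residues` strings are all the
#' same length (gap `'-'`) and include the reference row; ungapping the
#' reference row must reproduce the reference sequence exactly.
#'
#' @param msa aligned records data.frame (`id`, `taxon`, `residues`).
#' @param ref_id id of the reference row.
#' @param reference optional ungapped reference sequence to check against.
#' @return `msa`, invisibly, after validation.
#' @export
validate_msa <- function(msa, ref_id, reference = NULL) {
  stopifnot(ref_id %in% msa$id)
  lens <- nchar(msa$residues)
  if (length(unique(lens)) != 1L)
    stop("aligned rows differ in length")
  if (!is.null(reference)) {
    ref_row <- msa$residues[msa$id == ref_id]
    if (gsub("-", "", ref_row, fixed = TRUE) != reference)
      stop("ungapped reference row does not reproduce the reference sequence")
  }
  invisible(msa)
}

#' Map reference positions to alignment columns
#'
#' The k-th non-gap character of the reference row maps to its alignment
#' column. The mapping is bijective on its domain; the inverse
#' (column -> position) is attached as attribute `inverse`.
#'
#' @param msa aligned records data.frame.
#' @param ref_id id of the reference row.
#' @param positions integer reference positions.
#' @return named integer vector position -> column (1-based), with
#'   attribute `inverse`.
#' @export
ref_positions_to_columns <- function(msa, ref_id, positions) {
  stopifnot(ref_id %in% msa$id)
  ref <- strsplit(msa$residues[msa$id == ref_id], "")[[1]]
  cols <- which(ref != "-")
  if (any(positions < 1L | positions > length(cols)))
    stop("position beyond reference length (", length(cols), ")")
  out <- setNames(cols[positions], positions)
  attr(out, "inverse") <- setNames(as.integer(positions), cols[positions])
  out
}

#' Extract gate residues through an alignment
#'
#' Residues at the alignment columns homologous to the requested reference
#' positions, for every row of an MSA (`extract_gate_residues_msa`) or for a
#' single unaligned sequence via pairwise global alignment to the reference
#' (`extract_gate_residues`). Gaps are reported as `'-'`.
#'
#' @param msa aligned records data.frame.
#' @param ref_id reference row id.
#' @param positions integer reference positions (default: the four gate
#'   positions).
#' @return `extract_gate_residues_msa`: character matrix (records x
#'   positions, rownames = ids); `extract_gate_residues`: named character
#'   vector.
#' @export
extract_gate_residues_msa <- function(msa, ref_id,
                                      positions = gate_annotation()$gate_positions) {
  cols <- ref_positions_to_columns(msa, ref_id, positions)
  out <- t(vapply(msa$residues, function(s)
    vapply(cols, function(cc) substr(s, cc, cc), character(1)),
    character(length(cols))))
  dimnames(out) <- list(msa$id, names(cols))
  out
}

#' @rdname extract_gate_residues_msa
#' @param seq unaligned protein sequence (single string).
#' @param reference ungapped reference sequence.
#' @param ... passed to [align_global()].
#' @export
extract_gate_residues <- function(seq, reference,
                                  positions = gate_annotation()$gate_positions,
                                  ...) {
  aln <- align_global(seq, reference, ...)
  ref <- strsplit(aln$aligned_b, "")[[1]]
  qry <- strsplit(aln$aligned_a, "")[[1]]
  cols <- which(ref != "-")
  if (any(positions < 1L | positions > length(cols)))
    stop("position beyond reference length (", length(cols), ")")
  setNames(qry[cols[positions]], positions)
}

#' Per-taxon residue occurrence at gate positions
#'
#' Tabulates categorical residue frequencies (gap `'-'` is a 21st category)
#' per (reference position, taxon). Counts are retained; fractions sum to 1
#' within each (position, taxon).
#'
#' @param gate_long data.frame with columns `id`, `taxon`, `position`,
#'   `residue` (one row per record and position), e.g. a melted
#'   [extract_gate_residues_msa()] result.
#' @return data.frame of class `residue_frequency_table` with `position`,
#'   `taxon`, `residue`, `count`, `fraction`.
#' @export
occurrence_by_taxon <- function(gate_long) {
  stopifnot(all(c("taxon", "position", "residue") %in% names(gate_long)))
  agg <- stats::aggregate(cbind(count = rep(1L, nrow(gate_long))) ~
                            position + taxon + residue, data = gate_long, FUN = sum)
  totals <- stats::aggregate(count ~ position + taxon, data = agg, FUN = sum)
  names(totals)[3] <- "total"
  agg <- merge(agg, totals, by = c("position", "taxon"))
  agg$fraction <- agg$count / agg$total
  agg$total <- NULL
  agg <- agg[order(agg$position, agg$taxon, -agg$count, agg$residue), ]
  rownames(agg) <- NULL
  class(agg) <- c("residue_frequency_table", "data.frame")
  agg
}

#' Melt a gate-residue matrix to long form
#'
#' @param mat character matrix from [extract_gate_residues_msa()].
#' @param taxa taxon per row (recycled against rownames of `mat`).
#' @return long data.frame suitable for [occurrence_by_taxon()].
#' @export
gate_residues_long <- function(mat, taxa) {
  data.frame(id = rep(rownames(mat), times = ncol(mat)),
             taxon = rep(rep_len(taxa, nrow(mat)), times = ncol(mat)),
             position = rep(as.integer(colnames(mat)), each = nrow(mat)),
             residue = as.vector(mat), stringsAsFactors = FALSE)
}

#' Sequence-logo information content of a column
#'
#' \eqn{R = \log_2 20 - H} bits, with H the Shannon entropy of the column's
#' amino-acid distribution. Gaps are excluded from the 20-letter
#' distribution (track them separately); an all-gap column is undefined and
#' returns `NA` with a warning. The optional small-sample correction
#' subtracts \eqn{e_n = 19 / (2 n \ln 2)}.
#'
#' @param column_counts named counts (amino-acid letters; `'-'` entries are
#'   dropped).
#' @param small_sample_correction default `FALSE`.
#' @return information content in bits, in `[0, log2(20)]`.
#' @examples
#' information_content(c(F = 10)) # log2(20) = 4.3219
#' @export
information_content <- function(column_counts,
                                small_sample_correction = FALSE) {
  counts <- column_counts[names(column_counts) != "-"]
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) {
    warning("all-gap column: information content undefined")
    return(NA_real_)
  }
  p <- counts / n
  H <- -sum(p * log2(p))
  R <- log2(20) - H
  if (small_sample_correction) R <- R - 19 / (2 * n * log(2))
  min(max(R, 0), log2(20))
}

#' Consensus-motif caller
#'
#' Per position: emit the top residue if its fraction reaches `t_single`;
#' otherwise `"A/B"` if the top two sum to at least `t_pair` and each
#' reaches `t_member`; otherwise `"x"`. Tokens are joined with spaces,
#' reproducing patterns like `"G F x x S/P R/K x x"`.
#'
#' @param profile list of named fraction vectors, one per position, or a
#'   [occurrence_by_taxon()] table (optionally filtered to one taxon) whose
#'   positions become the profile.
#' @param t_single,t_pair,t_member thresholds in `(0, 1]` (defaults 0.5,
#'   0.5, 0.2).
#' @return single space-separated token string.
#' @export
consensus_motif <- function(profile, t_single = 0.5, t_pair = 0.5,
                            t_member = 0.2) {
  stopifnot(t_single > 0, t_single <= 1, t_pair > 0, t_pair <= 1,
            t_member > 0, t_member <= 1)
  if (inherits(profile, "residue_frequency_table")) {
    if (length(unique(profile$taxon)) > 1)
      stop("pool or filter to a single taxon before calling a consensus")
    profile <- lapply(split(profile, profile$position), function(d)
      setNames(d$fraction, d$residue))
  }
  tokens <- vapply(profile, function(fr) {
    fr <- sort(fr[names(fr) != "-"], decreasing = TRUE)
    if (length(fr) == 0L) return("x")
    if (fr[1] >= t_single) return(names(fr)[1])
    if (length(fr) >= 2L && fr[1] + fr[2] >= t_pair &&
        fr[1] >= t_member && fr[2] >= t_member)
      return(paste0(names(fr)[1], "/", names(fr)[2]))
    "x"
  }, character(1))
  paste(tokens, collapse = " ")
}
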