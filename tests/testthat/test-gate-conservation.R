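test_that("FASTA round trips preserve ids, taxa and sequences", {
  recs <- data.frame(id = c("s1", "s2"),
                     taxon = c("Brassicaceae", "unknown"),
                     residues = c("MKV", "ACDEFG"),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back, recs)
  # header dialect: pipe carries the taxon, absent pipe -> unknown
  writeLines(c(">a|Fabaceae", "mkv*", ">b", "ACD"), path)
  r <- read_fasta(path)
  expect_equal(r$taxon, c("Fabaceae", "unknown"))
  expect_equal(r$residues[1], "MKV") # uppercased, '*' stripped
  writeLines(c(">a", "MK", ">a", "MK"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(character(), path)
  expect_error(read_fasta(path), "empty")
})

test_that("motif search honours the X wildcard and overlaps", {
  expect_equal(find_motif("AALLAGPPKK", "LLXGPP"), 3L)
  expect_equal(find_motif("AALLGPPKK", "LLXGPP"), integer())
  expect_equal(find_motif("VCTIHQPVCTIHQP", "VCTIHQP"), c(1L, 8L))
  # overlapping matches are all reported
  expect_equal(find_motif("AAAA", "AXA"), 1:2)
  expect_equal(find_motif("MK", "LLXGPP"), integer())
  # sliding-window oracle on random strings
  set.seed(5)
  for (k in 1:20) {
    s <- paste(sample(c("A", "G", "L", "P"), 30, replace = TRUE),
               collapse = "")
    expect_equal(find_motif(s, "LXG"),
                 abcgate:::naive_motif_starts(strsplit(s, "")[[1]], "LXG"))
  }
})

test_that("the full-size filter applies length bounds then motifs", {
  spec <- filter_spec()
  pan <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(c(Brassicaceae = 5, Fabaceae = 5, Solanaceae = 5)),
    include_reference = FALSE, seed = 31))
  res <- filter_full_size(pan$records, spec)
  expect_equal(nrow(res$kept), 15)
  # inclusive boundaries
  b950 <- data.frame(id = "b", taxon = "unknown",
                     residues = substr(pan$records$residues[1], 1, 949))
  expect_equal(filter_full_size(b950, spec)$rejected$reason, "length")
  # first failing criterion is named
  mot <- pan$records[1, ]
  mot$residues <- gsub("VCTIHQP", "VCTAHQA", mot$residues)
  expect_equal(filter_full_size(mot, spec)$rejected$reason,
               "motif VCTIHQP")
  # idempotence and partition
  again <- filter_full_size(res$kept, spec)
  expect_equal(nrow(again$kept), nrow(res$kept))
  expect_equal(nrow(again$rejected), 0)
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(pan$records))
})

test_that("global alignment reproduces worked scores and Biostrings", {
  r <- align_global("FG", "FG")
  expect_equal(r$score, 12) # F-F = 6 and G-G = 6 in BLOSUM62
  expect_equal(r$aligned_a, "FG")
  e <- align_global("", "AA")
  expect_equal(e$score, -10 + 2 * (-0.5)) # one run of two gaps
  expect_equal(e$aligned_a, "--")
  expect_error(align_global("F!", "FG"), "absent")
  # independent implementation: Biostrings' aligner on longer pairs
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 35, replace = TRUE), collapse = "")
    ours <- align_global(a, b)$score
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global"))
    expect_equal(ours, ref)
  }
})

test_that("alignment equals exhaustive enumeration on short pairs", {
  S <- blosum62()
  alpha <- c("A", "C", "D", "E")
  seqs <- unlist(lapply(1:3, function(L)
    apply(expand.grid(rep(list(alpha), L)), 1, paste, collapse = "")))
  for (a in seqs[seq(1, length(seqs), by = 7)])
    for (b in seqs[seq(1, length(seqs), by = 11)])
      expect_equal(align_global(a, b)$score,
                   brute_align_score(a, b, S, -10, -0.5))
})

test_that("reference positions map to columns bijectively", {
  msa <- data.frame(id = c("AtABCG36", "x"), taxon = "unknown",
                    residues = c("FG-MI", "FGAMI"),
                    stringsAsFactors = FALSE)
  m <- ref_positions_to_columns(msa, "AtABCG36", 3)
  expect_equal(as.vector(m), 4L) # one gap before M
  expect_equal(unname(attr(m, "inverse")[["4"]]), 3L)
  # ungapped reference: identity
  msa2 <- data.frame(id = "AtABCG36", taxon = "unknown", residues = "FGMI")
  expect_equal(as.vector(ref_positions_to_columns(msa2, "AtABCG36", 1:4)),
               1:4)
  expect_error(ref_positions_to_columns(msa, "AtABCG36", 9), "beyond")
  # round trip over random gapped alignments
  for (seed in 1:5) {
    aln <- random_alignment(3, 25, seed = seed)
    mm <- ref_positions_to_columns(aln, "REF", 1:25)
    inv <- attr(mm, "inverse")
    expect_equal(unname(inv[as.character(unname(mm))]), 1:25)
  }
})

test_that("gate extraction reproduces every residue the segments contain", {
  named <- c(`585` = "I", `589` = "F", `592` = "F", `698` = "F",
             `1251` = "Y", `1259` = "I", `1260` = "N", `1369` = "N")
  expect_equal(segment_residue(as.integer(names(named))), named)
  # through an MSA of the scaffold against itself plus a derived record
  pan <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(c(Brassicaceae = 3, Fabaceae = 1, Solanaceae = 1)),
    seed = 13))
  msa <- pad_to_msa(pan$records)
  validate_msa(msa, "AtABCG36", abcg36_scaffold())
  got <- extract_gate_residues_msa(msa, "AtABCG36",
                                   as.integer(names(named)))
  expect_equal(unname(got["AtABCG36", ]), unname(named))
  # pairwise route on the scaffold itself
  pw <- extract_gate_residues(abcg36_scaffold(), abcg36_scaffold(),
                              as.integer(names(named)))
  expect_equal(pw, named)
})

test_that("per-taxon occurrence tables count and normalise correctly", {
  long <- data.frame(id = paste0("s", 1:4), taxon = "Brassicaceae",
                     position = 704L, residue = c("L", "L", "F", "V"))
  tab <- occurrence_by_taxon(long)
  expect_equal(tab$fraction[tab$residue == "L"], 0.5)
  expect_equal(tab$fraction[tab$residue == "F"], 0.25)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(sum(tab$count), 4)
  # degenerate single record
  one <- occurrence_by_taxon(long[1, ])
  expect_equal(one$fraction, 1)
  # pooling two taxa equals the count-weighted mixture
  long2 <- rbind(long,
                 data.frame(id = paste0("t", 1:2), taxon = "Fabaceae",
                            position = 704L, residue = c("F", "F")))
  pooled <- long2
  pooled$taxon <- "all"
  tp <- occurrence_by_taxon(pooled)
  expect_equal(tp$fraction[tp$residue == "F"], (1 + 2) / 6)
})

test_that("information content follows the logo formula", {
  expect_equal(information_content(c(F = 100)), log2(20))
  expect_equal(information_content(setNames(rep(5, 20),
                                            strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]])), 0)
  expect_equal(information_content(c(L = 50, V = 50)), log2(20) - 1)
  # gaps excluded from the 20-letter distribution
  expect_equal(information_content(c(F = 10, `-` = 90)), log2(20))
  expect_warning(r <- information_content(c(`-` = 10)), "all-gap")
  expect_true(is.na(r))
  # small-sample correction subtracts 19 / (2 n ln 2)
  expect_equal(information_content(c(F = 10), small_sample_correction = TRUE),
               log2(20) - 19 / (2 * 10 * log(2)))
})

test_that("the consensus caller reproduces the gate motif pattern", {
  expect_equal(consensus_motif(list(c(G = 0.95))), "G")
  expect_equal(consensus_motif(list(c(S = 0.35, P = 0.30, A = 0.05))),
               "S/P")
  spread <- c(A = 0.1, C = 0.1, D = 0.1, E = 0.1, F = 0.1, G = 0.1,
              H = 0.1, I = 0.1, K = 0.1, L = 0.1)
  profile <- list(c(G = 0.9, A = 0.1), c(F = 0.9, L = 0.1), spread, spread,
                  c(S = 0.3, P = 0.3, A = 0.2, C = 0.2),
                  c(R = 0.3, K = 0.3, A = 0.2, C = 0.2), spread, spread)
  expect_equal(consensus_motif(profile), "G F x x S/P R/K x x")
})
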