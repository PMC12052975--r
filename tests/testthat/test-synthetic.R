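test_that("landscape archetypes encode the documented shapes", {
  dw <- make_landscape("double_well", list(barrier = 12, minima = 0.8))
  expect_equal(evaluate_landscape(dw, c(-0.8, 0, 0.8))$energy, c(0, 12, 0))
  expect_true(all(evaluate_landscape(make_landscape("flat"),
                                     seq(-1, 2, 0.5))$energy == 0))
  # the non-substrate profile differs from the substrate one by a bump
  # whose maximum lies in the entry region [-1, -0.5]
  zg <- seq(-1.4, 2.2, by = 0.01)
  sub <- evaluate_landscape(make_landscape("substrate_downhill"), zg)$energy
  non <- evaluate_landscape(make_landscape("nonsubstrate_entry_barrier"),
                            zg)$energy
  dmax <- zg[which.max(non - sub)]
  expect_gte(dmax, -1)
  expect_lte(dmax, -0.5)
  expect_equal(max(non - sub), 8, tolerance = 1e-6)
  # substrate profile: downhill trend with modest local barriers
  expect_lt(sub[length(zg)], sub[1])
  expect_error(make_landscape("no_such_shape"), "unknown")
})

test_that("the transport label table matches the phenotype grid", {
  lab <- make_transport_labels()
  expect_equal(nrow(lab), 36)
  g <- function(m, v) lab$transported[lab$molecule == m & lab$variant == v]
  expect_equal(g("IBA", "L704F"), 1L)
  expect_equal(g("IBA", "A1357V"), 0L)
  expect_equal(g("CLX", "L704F"), 0L)
  expect_equal(g("CLX", "Wt"), 1L)
  expect_equal(g("CLX", "L704Y"), 1L)
  expect_equal(g("IAA", "L704Y"), 1L)
  expect_equal(g("IAA", "L704S"), 1L)
  expect_equal(g("IAA", "Wt"), 0L)
  expect_equal(g("IND", "L704Y"), 1L)
  expect_equal(g("IND", "L704W"), 0L)
  # complete grid, deterministic
  expect_identical(lab, make_transport_labels())
})

test_that("pull panels are deterministic with planted effects", {
  p1 <- make_pull_panel(panel_spec(n_replicates = 1, seed = 4))
  p2 <- make_pull_panel(panel_spec(n_replicates = 1, seed = 4))
  expect_identical(p1$tables, p2$tables)
  # planted shifts separate the class means of promote residues
  adj <- t(vapply(p1$tables, function(t)
    setNames(t$adjusted_frequency, t$residue), numeric(20)))
  y <- p1$labels$transported
  gap <- colMeans(adj[y == 1, p1$truth$promote]) -
    colMeans(adj[y == 0, p1$truth$promote])
  expect_true(all(gap > 0.15))
  # null construction: no effect -> near-chance recovery
  spec0 <- panel_spec(n_replicates = 1, effect_size = 1e-6, seed = 4)
  p0 <- make_pull_panel(spec0)
  dm <- build_design_matrix(p0$tables, p0$labels)
  fit <- fit_logistic(dm$X, dm$y, lambda = 1)
  imp <- residue_importance(fit)
  cls <- setNames(imp$class, imp$residue)
  hits <- sum(cls[p0$truth$promote] == "promote") +
    sum(cls[p0$truth$counteract] == "counteract")
  expect_lt(hits, 11) # not all 11 planted signs recovered without signal
})

test_that("mechanistic and direct panels agree on the effect ordering", {
  # in both generator modes, transported simulations see promoting residues
  # more than counteracting ones, and the ordering flips for
  # non-transported simulations
  spec <- panel_spec(molecules = "CLX", variants = c("Wt", "L704F"),
                     n_replicates = 4, seed = 6)
  orderings <- function(panel) {
    raw <- t(vapply(panel$tables, function(t)
      setNames(t$raw_frequency, t$residue), numeric(20)))
    y <- panel$labels$transported[match(
      paste(vapply(panel$tables, function(t) attr(t, "metadata")$molecule, ""),
            vapply(panel$tables, function(t) attr(t, "metadata")$variant, "")),
      paste(panel$labels$molecule, panel$labels$variant))]
    c(transported = mean(raw[y == 1, panel$truth$promote]) -
        mean(raw[y == 1, panel$truth$counteract]),
      untransported = mean(raw[y == 0, panel$truth$counteract]) -
        mean(raw[y == 0, panel$truth$promote]))
  }
  expect_true(all(orderings(make_pull_panel(spec, mode = "direct")) > 0))
  expect_true(all(orderings(make_pull_panel(spec, mode = "mechanistic")) > 0))
})

test_that("sequence panels carry their gate-residue ground truth", {
  spec <- sequence_panel_spec(
    taxa = default_taxa(c(Brassicaceae = 8, Fabaceae = 4, Solanaceae = 4)),
    seed = 17)
  pan <- make_sequence_panel(spec)
  expect_identical(pan, make_sequence_panel(spec)) # pure function of spec
  expect_equal(nrow(pan$records), 17) # 16 + reference
  expect_equal(pan$records$id[1], "AtABCG36")
  # every record satisfies the filter when planting is on
  expect_equal(nrow(filter_full_size(pan$records)$kept), 17)
  # drawn gate residues match the emitted sequences
  msa <- pad_to_msa(pan$records)
  got <- extract_gate_residues_msa(msa, "AtABCG36")
  for (k in seq_len(nrow(pan$truth))) {
    tr <- pan$truth[k, ]
    expect_equal(unname(got[tr$id, as.character(tr$position)]), tr$residue)
  }
  # planting off: the filter rejects everything for missing motifs
  off <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(c(Brassicaceae = 5, Fabaceae = 2, Solanaceae = 2)),
    plant_motifs = FALSE, include_reference = FALSE, seed = 18))
  res <- filter_full_size(off$records)
  expect_equal(nrow(res$kept), 0)
  expect_true(all(grepl("^motif", res$rejected$reason)))
})

test_that("occurrence recovery approaches the planted distributions", {
  spec <- sequence_panel_spec(
    taxa = default_taxa(c(Brassicaceae = 500, Fabaceae = 120,
                          Solanaceae = 120)),
    include_reference = FALSE, seed = 23)
  pan <- make_sequence_panel(spec)
  tab <- occurrence_by_taxon(pan$truth)
  for (pos in c("703", "704", "1374", "1375")) {
    planted <- spec$taxa$Brassicaceae$gate[[pos]]
    emp <- tab[tab$taxon == "Brassicaceae" & tab$position == as.integer(pos), ]
    empv <- setNames(emp$fraction, emp$residue)
    all_res <- union(names(planted), names(empv))
    tv <- 0.5 * sum(abs(ifelse(is.na(planted[all_res]), 0, planted[all_res]) -
                          ifelse(is.na(empv[all_res]), 0, empv[all_res])))
    expect_lt(tv, 0.05)
  }
})
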