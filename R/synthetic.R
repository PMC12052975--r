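#' Landscape archetypes
#'
#' Deterministic constructors for the translocation free-energy archetypes:
#' \describe{
#'   \item{substrate_downhill}{overall downhill profile from -1.1 to 2.0 nm
#'     decorated with local barriers of at most 6 kJ/mol — the shape of a
#'     transported substrate.}
#'   \item{nonsubstrate_entry_barrier}{the same profile plus an additional
#'     Gaussian entry barrier (default +8 kJ/mol, centred at -0.75 nm,
#'     within the -1 to -0.5 nm entry region) — the shape associated with a
#'     substrate whose pocket access is impeded.}
#'   \item{double_well}{symmetric quartic double well, `barrier` kJ/mol at
#'     z = 0 and minima at `+/- minima` nm.}
#'   \item{harmonic, flat}{as in [landscape()].}
#' }
#' All parameters are recorded in the object, so the analytic profile is
#' exactly known.
#'
#' @param archetype one of `"substrate_downhill"`,
#'   `"nonsubstrate_entry_barrier"`, `"double_well"`, `"harmonic"`,
#'   `"flat"`.
#' @param params named list overriding archetype defaults; for the entry
#'   barrier: `entry_height` (kJ/mol), `entry_center`, `entry_width` (nm).
#' @param seed accepted for generator-interface uniformity; the archetypes
#'   are deterministic and ignore it.
#' @return an [landscape()] object.
#' @examples
#' dw <- make_landscape("double_well", list(barrier = 12, minima = 0.8))
#' evaluate_landscape(dw, c(-0.8, 0, 0.8))$energy # 0, 12, 0
#' @export
make_landscape <- function(archetype, params = list(), seed = NULL) {
  switch(archetype,
    flat = landscape("flat"),
    harmonic = landscape("harmonic", params),
    double_well = landscape("double_well", params),
    substrate_downhill = landscape("downhill_barriers", params),
    nonsubstrate_entry_barrier = {
      eh <- params$entry_height %||% 8
      ec <- params$entry_center %||% -0.75
      ew <- params$entry_width %||% 0.12
      params[c("entry_height", "entry_center", "entry_width")] <- NULL
      base <- landscape("downhill_barriers", params)$params
      landscape("entry_barrier", list(
        slope = base$slope, ref = base$ref,
        barrier_heights = c(eh, base$barrier_heights),
        barrier_centers = c(ec, base$barrier_centers),
        barrier_widths = c(ew, base$barrier_widths)))
    },
    stop("unknown landscape archetype: ", archetype))
}

#' Transport phenotype table
#'
#' The transported / not-transported outcome of every molecule x variant
#' combination in the mutational panel: IBA is exported by every L704
#' variant but not by A1357V; CLX only by Wt and L704Y; IAA is gained by
#' L704Y and L704S; indole only by L704Y.
#'
#' @param molecules,variants the grid (defaults: IBA, CLX, IAA, IND x Wt and
#'   the eight point mutants).
#' @return complete data.frame `molecule`, `variant`, `transported` (0/1).
#' @export
make_transport_labels <- function(molecules = c("IBA", "CLX", "IAA", "IND"),
                                  variants = c("Wt", "L704F", "L704Y",
                                               "L704S", "L704A", "L704R",
                                               "L704D", "L704W", "A1357V")) {
  grid <- expand.grid(molecule = molecules, variant = variants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  transported <- with(grid,
    ifelse(molecule == "IBA", as.integer(variant != "A1357V"),
    ifelse(molecule == "CLX", as.integer(variant %in% c("Wt", "L704Y")),
    ifelse(molecule == "IAA", as.integer(variant %in% c("L704Y", "L704S")),
    ifelse(molecule == "IND", as.integer(variant == "L704Y"), 0L)))))
  grid$transported <- transported
  grid[order(grid$molecule, grid$variant), c("molecule", "variant", "transported")] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Pulling-panel generator specification
#'
#' Ground-truth residue effects for the synthetic contact-frequency panels:
#' seven promoting and four counteracting residues (the gate-pathway
#' residues highlighted by the importance analysis) plus neutral background
#' residues. Contact-frequency magnitudes are generator conventions
#' (baseline 0.2, effect 0.3) chosen so recovery is neither trivial nor
#' impossible.
#'
#' @param molecules,variants panel grid (defaults as
#'   [make_transport_labels()]).
#' @param n_replicates pulls per combination (default 25).
#' @param promote_residues,counteract_residues,background_residues residue
#'   label sets (promote/counteract must be disjoint).
#' @param baseline mean adjusted frequency of an unaffected residue.
#' @param effect_size contact-frequency shift for planted residues, in
#'   (0, 1) (default 0.3).
#' @param noise_sd replicate noise (default 0.05).
#' @param seed generator seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(molecules = c("IBA", "CLX", "IAA", "IND"),
                       variants = c("Wt", "L704F", "L704Y", "L704S",
                                    "L704A", "L704R", "L704D", "L704W",
                                    "A1357V"),
                       n_replicates = 25L,
                       promote_residues = c("I585", "F698", "L704", "L705",
                                            "Y1251", "A1252", "N1369"),
                       counteract_residues = c("F589", "F592", "I1259",
                                               "N1260"),
                       background_residues = c("G584", "T586", "S590",
                                               "A593", "V596", "L687",
                                               "I1253", "V1360", "F1362"),
                       baseline = 0.2, effect_size = 0.3, noise_sd = 0.05,
                       seed = 1L) {
  stopifnot(effect_size > 0, effect_size < 1, noise_sd >= 0,
            length(intersect(promote_residues, counteract_residues)) == 0)
  structure(list(molecules = molecules, variants = variants,
                 n_replicates = as.integer(n_replicates),
                 promote_residues = promote_residues,
                 counteract_residues = counteract_residues,
                 background_residues = background_residues,
                 baseline = baseline, effect_size = effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}

#' Generate a labelled contact-frequency panel
#'
#' For each (molecule, variant, replicate): baseline adjusted frequencies
#' drawn from a clipped Gaussian(baseline, noise_sd) per residue; if the
#' combination is transported, promoting residues are shifted by
#' `+effect_size` and counteracting residues by `-effect_size/2`; if not
#' transported, counteracting residues are shifted by `+effect_size/2`.
#' Values are clipped to `[-1, 1]`. `mode = "mechanistic"` instead routes
#' every replicate through [run_constant_velocity_pull()] on the matched
#' landscape archetype (substrate vs entry-barrier), with residue zones
#' placed near the extracellular gate for promoting residues and in the
#' entry region for counteracting ones.
#'
#' @param spec a [panel_spec()].
#' @param mode `"direct"` (default) or `"mechanistic"`.
#' @return list with `tables` (list of [contact_frequency_table()]s),
#'   `labels` ([make_transport_labels()] restricted to the grid), and
#'   `truth` (the planted residue sets).
#' @export
make_pull_panel <- function(spec = panel_spec(), mode = c("direct",
                                                          "mechanistic")) {
  mode <- match.arg(mode)
  labels <- make_transport_labels(spec$molecules, spec$variants)
  residues <- c(spec$promote_residues, spec$counteract_residues,
                spec$background_residues)
  tables <- list()
  n_clip <- 0L; n_val <- 0L
  counter <- 0L
  for (i in seq_len(nrow(labels))) {
    lab <- labels$transported[i]
    for (rep_i in seq_len(spec$n_replicates)) {
      counter <- counter + 1L
      meta <- list(molecule = labels$molecule[i],
                   variant = labels$variant[i], replicate = rep_i,
                   seed = spec$seed + counter)
      if (mode == "direct") {
        adj <- with_seed(spec$seed + counter,
                         rnorm(length(residues), spec$baseline, spec$noise_sd))
        names(adj) <- residues
        if (lab == 1L) {
          adj[spec$promote_residues] <- adj[spec$promote_residues] + spec$effect_size
          adj[spec$counteract_residues] <- adj[spec$counteract_residues] - spec$effect_size / 2
        } else {
          adj[spec$counteract_residues] <- adj[spec$counteract_residues] + spec$effect_size / 2
        }
        clipped <- adj < -1 | adj > 1
        n_clip <- n_clip + sum(clipped); n_val <- n_val + length(adj)
        adj <- pmin(pmax(adj, -1), 1)
        raw <- pmin(abs(adj) + 0.1, 1)
        tables[[counter]] <- contact_frequency_table(residues, raw, adj, meta)
      } else {
        # trapping regime: on the ~300 ps desk pull an entry barrier is
        # rate-limiting only well above kT, so the mechanistic archetype for
        # non-transported systems uses an 18 kJ/mol (~7 kT) entry bump and a
        # weak dragging spring
        land <- if (lab == 1L) make_landscape("substrate_downhill")
                else make_landscape("nonsubstrate_entry_barrier",
                                    list(entry_height = 18))
        zones <- panel_zones(spec)
        traj <- run_constant_velocity_pull(
          land, pull_config(force_constant = 10, velocity = 10),
          langevin_params(), wall_spec(), zones, z_start = -1.1,
          n_steps = 155000L, seed = spec$seed + counter)
        tab <- adjusted_contact_frequencies(traj)
        attr(tab, "metadata") <- meta
        tables[[counter]] <- tab
      }
    }
  }
  if (n_val > 0 && n_clip / n_val > 0.5)
    warning("effect/noise settings clipped ", round(100 * n_clip / n_val),
            "% of the generated frequencies")
  list(tables = tables, labels = labels,
       truth = list(promote = spec$promote_residues,
                    counteract = spec$counteract_residues,
                    background = spec$background_residues))
}

# promoting residues sit near the extracellular gate (> 1.3 nm),
# counteracting ones in the entry region, background in between
panel_zones <- function(spec) {
  np <- length(spec$promote_residues)
  nc <- length(spec$counteract_residues)
  nb <- length(spec$background_residues)
  residue_zones(
    c(spec$promote_residues, spec$counteract_residues,
      spec$background_residues),
    c(seq(1.35, 1.95, length.out = np), seq(-0.9, 0.1, length.out = nc),
      seq(0.25, 1.25, length.out = nb)))
}

# ---------------------------------------------------------------------------
# ABCG-like sequence panels

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

scaffold_motif_instances <- function() {
  # PDR signature motifs with wildcards instantiated, at fixed coordinates
  # clear of the helix segments and gate positions
  data.frame(start = c(60L, 130L, 210L, 1000L),
             seq = c("LLAGPP", "GLTSS", "GLDARIAATVMR", "VCTIHQP"),
             stringsAsFactors = FALSE)
}

#' The synthetic AtABCG36-like reference scaffold
#'
#' A deterministic synthetic stand-in for the AtABCG36 reference sequence
#' (the real protein is not bundled): random background with the four
#' printed helix segments embedded at 582-597, 685-700, 1250-1265 and
#' 1356-1371, gate residues F703/L704/F1374/F1375, and the four PDR
#' signature motifs planted at fixed positions so the scaffold passes the
#' full-size filter. The background is rejection-sampled so no motif
#' matches anywhere except at the planted sites.
#'
#' @param seed scaffold seed (default 101).
#' @param core_length length of the aligned core (default 1420).
#' @param tail_length unaligned C-terminal tail of the reference (default
#'   49).
#' @return single character string.
#' @export
abcg36_scaffold <- function(seed = 101L, core_length = 1420L,
                            tail_length = 49L) {
  stopifnot(core_length >= 1400L)
  ann <- gate_annotation()
  with_seed(seed, {
    chars <- sample(AA20, core_length + tail_length, replace = TRUE)
    for (i in seq_len(nrow(ann$helix_segments))) {
      s <- ann$helix_segments[i, ]
      chars[s$start:s$end] <- strsplit(s$seq, "")[[1]]
    }
    chars[c(703L, 704L, 1374L, 1375L)] <- c("F", "L", "F", "F")
    mot <- scaffold_motif_instances()
    protected <- integer()
    for (i in seq_len(nrow(mot))) {
      idx <- mot$start[i]:(mot$start[i] + nchar(mot$seq[i]) - 1L)
      chars[idx] <- strsplit(mot$seq[i], "")[[1]]
      protected <- c(protected, idx)
    }
    protected <- c(protected,
                   unlist(Map(seq, ann$helix_segments$start,
                              ann$helix_segments$end)),
                   703L, 704L, 1374L, 1375L)
    chars <- scrub_accidental_motifs(chars, protected)
    paste(chars, collapse = "")
  })
}

# independent sliding-window motif scan (no regex; used only by generators)
naive_motif_starts <- function(chars, pattern) {
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc)
  n <- length(chars)
  if (L > n) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (i in seq_len(L)) {
    if (pc[i] == "X") next
    ok <- ok & chars[seq.int(i, n - L + i)] == pc[i]
  }
  which(ok)
}

# redraw background residues until no PDR motif matches outside planted sites
scrub_accidental_motifs <- function(chars, protected,
                                    patterns = filter_spec()$motifs) {
  planted_ok <- scaffold_motif_instances()$start
  for (pass in 1:50) {
    dirty <- FALSE
    for (p in patterns) {
      for (s in naive_motif_starts(chars, p)) {
        if (s %in% planted_ok) next
        idx <- s:(s + nchar(p) - 1L)
        idx <- setdiff(idx, protected)
        if (length(idx) == 0L) next # fully inside protected regions: leave
        chars[idx] <- sample(AA20, length(idx), replace = TRUE)
        dirty <- TRUE
      }
    }
    if (!dirty) return(chars)
  }
  chars
}

#' Sequence-panel generator specification
#'
#' Per-taxon panel sizes and categorical gate-residue distributions at the
#' four gate positions. Defaults use round numbers qualitatively matching
#' the taxon contrasts (the first gate position strongly phenylalanine in
#' all families; the second more variable, with extra leucine/valine weight
#' in Brassicaceae).
#'
#' @param taxa named list: each element a list with `n` and `gate`, the
#'   latter a list mapping position (as character) to a named fraction
#'   vector.
#' @param sub_rate background substitution rate per position relative to
#'   the scaffold (default 0.1).
#' @param tail_range unaligned C-terminal tail length range (default
#'   `c(0, 300)`).
#' @param plant_motifs keep the PDR motifs intact (default TRUE); `FALSE`
#'   scrambles them so the panel fails the full-size filter.
#' @param include_reference emit the reference scaffold as the first record
#'   (default TRUE).
#' @param seed generator seed.
#' @return object of class `sequence_panel_spec`.
#' @export
sequence_panel_spec <- function(taxa = default_taxa(), sub_rate = 0.1,
                                tail_range = c(0L, 300L),
                                plant_motifs = TRUE,
                                include_reference = TRUE, seed = 1L) {
  stopifnot(length(taxa) >= 1, sub_rate >= 0, sub_rate < 1,
            tail_range[1] >= 0, tail_range[2] >= tail_range[1])
  for (tx in taxa) {
    stopifnot(tx$n >= 1)
    for (d in tx$gate)
      stopifnot(abs(sum(d) - 1) < 1e-9, all(d >= 0))
  }
  structure(list(taxa = taxa, sub_rate = sub_rate,
                 tail_range = as.integer(tail_range),
                 plant_motifs = isTRUE(plant_motifs),
                 include_reference = isTRUE(include_reference),
                 seed = as.integer(seed)),
            class = "sequence_panel_spec")
}

#' @rdname sequence_panel_spec
#' @param n_per_taxon panel sizes for the three default families (defaults
#'   598, 762, 450 — the screened panel sizes).
#' @export
default_taxa <- function(n_per_taxon = c(Brassicaceae = 598L,
                                         Fabaceae = 762L,
                                         Solanaceae = 450L)) {
  g_strong_F <- c(F = 0.80, L = 0.10, V = 0.05, I = 0.05)
  g_1374 <- c(F = 0.85, L = 0.10, V = 0.05)
  list(
    Brassicaceae = list(n = n_per_taxon[["Brassicaceae"]], gate = list(
      `703` = g_strong_F,
      `704` = c(F = 0.40, L = 0.35, V = 0.20, I = 0.05),
      `1374` = g_1374,
      `1375` = c(F = 0.45, L = 0.35, V = 0.10, I = 0.10))),
    Fabaceae = list(n = n_per_taxon[["Fabaceae"]], gate = list(
      `703` = g_strong_F,
      `704` = c(F = 0.70, L = 0.15, V = 0.10, I = 0.05),
      `1374` = g_1374,
      `1375` = c(F = 0.65, L = 0.20, V = 0.10, I = 0.05))),
    Solanaceae = list(n = n_per_taxon[["Solanaceae"]], gate = list(
      `703` = g_strong_F,
      `704` = c(F = 0.75, L = 0.10, V = 0.10, I = 0.05),
      `1374` = g_1374,
      `1375` = c(F = 0.65, L = 0.20, V = 0.10, I = 0.05))))
}

#' Generate a taxon-structured ABCG-like sequence panel
#'
#' Each record derives from the reference scaffold core: background
#' positions substituted at `sub_rate`, gate residues drawn from the
#' taxon's distributions at the scaffold-homologous positions, PDR motifs
#' kept intact (or scrambled when planting is off), and a random unaligned
#' C-terminal tail within `tail_range`. Record coordinates therefore match
#' the scaffold's, so [pad_to_msa()] yields a valid alignment; records are
#' also alignable to the reference pairwise.
#'
#' @param spec a [sequence_panel_spec()].
#' @return list with `records` (data.frame `id`, `taxon`, `residues`) and
#'   `truth` (data.frame `id`, `taxon`, `position`, `residue` of every
#'   drawn gate residue).
#' @export
make_sequence_panel <- function(spec = sequence_panel_spec()) {
  stopifnot(inherits(spec, "sequence_panel_spec"))
  scaffold <- abcg36_scaffold()
  core_len <- 1420L
  core <- strsplit(substr(scaffold, 1L, core_len), "")[[1]]
  ann <- gate_annotation()
  mot <- scaffold_motif_instances()
  motif_idx <- unlist(Map(function(s, q) s:(s + nchar(q) - 1L),
                          mot$start, mot$seq))
  seg_idx <- unlist(Map(seq, ann$helix_segments$start,
                        ann$helix_segments$end))
  gate_pos <- ann$gate_positions
  protected <- c(motif_idx, seg_idx, gate_pos)

  with_seed(spec$seed, {
    recs <- list(); truths <- list(); k <- 0L
    for (taxon in names(spec$taxa)) {
      tx <- spec$taxa[[taxon]]
      for (i in seq_len(tx$n)) {
        k <- k + 1L
        chars <- core
        # background substitutions
        mut <- which(runif(core_len) < spec$sub_rate)
        mut <- setdiff(mut, protected)
        if (length(mut))
          chars[mut] <- sample(AA20, length(mut), replace = TRUE)
        # taxon-specific gate residues
        drawn <- vapply(as.character(gate_pos), function(p) {
          d <- tx$gate[[p]]
          sample(names(d), 1L, prob = d)
        }, character(1))
        chars[gate_pos] <- drawn
        if (!spec$plant_motifs) {
          chars[motif_idx] <- sample(AA20, length(motif_idx), replace = TRUE)
          chars <- scrub_all_motifs(chars, setdiff(protected, motif_idx))
        }
        tail_len <- sample(seq(spec$tail_range[1], spec$tail_range[2]), 1L)
        tail <- if (tail_len > 0) sample(AA20, tail_len, replace = TRUE) else character()
        full <- c(chars, tail)
        # no accidental motifs outside the planted sites
        full <- if (spec$plant_motifs)
          scrub_accidental_motifs(full, protected)
        else scrub_all_motifs(full, setdiff(protected, motif_idx))
        id <- sprintf("%s_%04d", substr(taxon, 1, 4), i)
        recs[[k]] <- data.frame(id = id, taxon = taxon,
                                residues = paste(full, collapse = ""),
                                stringsAsFactors = FALSE)
        truths[[k]] <- data.frame(id = id, taxon = taxon,
                                  position = gate_pos, residue = unname(drawn),
                                  stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    if (spec$include_reference)
      records <- rbind(data.frame(id = ann$reference_id, taxon = "reference",
                                  residues = scaffold,
                                  stringsAsFactors = FALSE), records)
    list(records = records, truth = do.call(rbind, truths))
  })
}

# remove every motif match (used when planting is off)
scrub_all_motifs <- function(chars, protected,
                             patterns = filter_spec()$motifs) {
  for (pass in 1:50) {
    dirty <- FALSE
    for (p in patterns) {
      for (s in naive_motif_starts(chars, p)) {
        idx <- setdiff(s:(s + nchar(p) - 1L), protected)
        if (length(idx) == 0L) next
        chars[idx] <- sample(AA20, length(idx), replace = TRUE)
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  chars
}

#' Pad a scaffold-derived panel into an alignment
#'
#' Records generated by [make_sequence_panel()] share the scaffold's core
#' coordinates and differ only in unaligned C-terminal tails; padding every
#' row with `'-'` to the maximum length therefore yields a valid MSA with
#' the reference row intact.
#'
#' @param records data.frame (`id`, `taxon`, `residues`).
#' @return records data.frame with equal-length `residues`.
#' @export
pad_to_msa <- function(records) {
  w <- max(nchar(records$residues))
  records$residues <- vapply(records$residues, function(s)
    paste0(s, strrep("-", w - nchar(s))), character(1), USE.NAMES = FALSE)
  records
}

#' Generate a mixed panel for filter benchmarking
#'
#' A panel with known keep/reject ground truth: `n_keep` intact full-size
#' records, `n_motif_fail` records with the PDR motifs scrambled, and
#' `n_len_fail` records truncated below the 950-residue bound.
#'
#' @param n_keep,n_motif_fail,n_len_fail panel composition (defaults 600,
#'   250, 150).
#' @param seed generator seed.
#' @return list with `records` and logical `truth_keep` aligned to rows.
#' @export
make_filter_panel <- function(n_keep = 600L, n_motif_fail = 250L,
                              n_len_fail = 150L, seed = 1L) {
  split3 <- function(n) {
    b <- round(n * c(0.4, 0.35, 0.25))
    b[1] <- n - sum(b[-1])
    c(Brassicaceae = b[1], Fabaceae = b[2], Solanaceae = b[3])
  }
  pos <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(split3(n_keep)), include_reference = FALSE,
    seed = seed))$records
  pos$id <- paste0("keep_", pos$id)
  neg_m <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(split3(n_motif_fail)), plant_motifs = FALSE,
    include_reference = FALSE, seed = seed + 1L))$records
  neg_m$id <- paste0("nomotif_", neg_m$id)
  neg_l <- make_sequence_panel(sequence_panel_spec(
    taxa = default_taxa(split3(n_len_fail)), include_reference = FALSE,
    seed = seed + 2L))$records
  neg_l$residues <- substr(neg_l$residues, 1L, 900L)
  neg_l$id <- paste0("short_", neg_l$id)
  records <- rbind(pos, neg_m, neg_l)
  list(records = records,
       truth_keep = c(rep(TRUE, nrow(pos)),
                      rep(FALSE, nrow(neg_m) + nrow(neg_l))))
}
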