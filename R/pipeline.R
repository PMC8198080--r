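# End-to-end orchestration: run every analysis stage on a configured
# input set and emit the full table suite as TSV files plus a JSON-ready
# summary. Stages whose inputs are absent are skipped with a notice.

#' Analysis configuration
#'
#' @param fasta Named character vector: species label -> FASTA path; or a
#'   coding-sequence set data frame (column `species` set).
#' @param reference_tables Named list: species -> `ref_usage` object or
#'   path (for CAI). Optional.
#' @param trna_tables Named list: species -> `trna_table` object or path.
#'   Optional.
#' @param alignment Optional pre-aligned multi-FASTA path or
#'   coding-sequence set for the phylogeny stage.
#' @param out_dir Output directory for the emitted tables.
#' @param include_stops Count stop codons in composition profiles.
#' @param expected_mode Dinucleotide expectation: `"uniform"` or
#'   `"mono_product"`.
#' @param p2_mode `"rscu"` or `"counts"`.
#' @param strict_validation Abort on invalid CDS records instead of
#'   excluding them.
#' @param rounding Decimal places for report tables.
#' @return A config list for [run_pipeline()].
#' @export
analysis_config <- function(fasta, reference_tables = NULL,
                            trna_tables = NULL, alignment = NULL,
                            out_dir = tempfile("cub_run_"),
                            include_stops = TRUE,
                            expected_mode = "uniform",
                            p2_mode = "rscu",
                            strict_validation = FALSE,
                            rounding = 4L) {
  list(fasta = fasta, reference_tables = reference_tables,
       trna_tables = trna_tables, alignment = alignment,
       out_dir = out_dir, include_stops = include_stops,
       expected_mode = expected_mode, p2_mode = p2_mode,
       strict_validation = strict_validation, rounding = rounding)
}

.load_inputs <- function(config) {
  if (is.data.frame(config$fasta)) return(config$fasta)
  sets <- Map(function(path, sp) read_cds_fasta(path, species = sp),
              config$fasta, names(config$fasta))
  do.call(rbind, unname(sets))
}

.emit <- function(df, name, dir, rounding) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = rounding)
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full codon-usage-bias pipeline
#'
#' Stages, in dependency order: validation, composition, dinucleotide
#' odds ratios, per-species RSCU (plus average and clustering), ENc/CAI
#' per sequence, P2 per species, neutrality, PR2, ENc-GC3 deviations,
#' correlation and regression tables, tRNA adaptation reports, and the
#' K2P neighbor-joining tree when an alignment is supplied. Deterministic
#' given the inputs.
#'
#' @param config A list from [analysis_config()].
#' @return Object of class `analysis_bundle`: list with `manifest`
#'   (emitted file paths), `summary` (key numbers), `skipped` (stage
#'   notices), and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rounding <- config$rounding
  manifest <- character(0)
  skipped <- character(0)
  note <- function(name, path) manifest[[name]] <<- path

  cds <- .load_inputs(config)
  vrep <- validate_cds_set(cds)
  note("validation", .emit(vrep, "validation", config$out_dir, rounding))
  cds <- filter_valid_cds(cds, strict = config$strict_validation,
                          quiet = TRUE)
  if (nrow(cds) == 0L) stop("no valid coding sequences")
  species <- unique(cds$species)

  profiles <- composition_profiles(cds, include_stop = config$include_stops)
  note("composition", .emit(profiles, "composition", config$out_dir, rounding))
  summ <- summarize_profiles(profiles)
  note("composition_summary",
       .emit(summ, "composition_summary", config$out_dir, rounding))

  obs <- dinucleotide_frequencies(cds)
  mono <- {
    allb <- strsplit(paste(cds$bases, collapse = ""), "", fixed = TRUE)[[1]]
    tab <- table(factor(allb, levels = BASES))
    stats::setNames(as.numeric(tab) / sum(tab), BASES)
  }
  dinuc <- odds_ratios(obs, expected_mode = config$expected_mode,
                       mono_freqs = mono)
  note("dinucleotides",
       .emit(as.data.frame(dinuc), "dinucleotides", config$out_dir, 7L))

  per_species_counts <- lapply(species, function(sp) {
    count_codons(cds[cds$species == sp, , drop = FALSE],
                 include_stops = FALSE)
  })
  names(per_species_counts) <- species
  rscu_tables <- lapply(species, function(sp) {
    rscu(per_species_counts[[sp]], label = sp)
  })
  names(rscu_tables) <- species
  rscu_wide <- data.frame(
    codon = sense_codons(),
    amino_acid = codon_to_aa(sense_codons()),
    stringsAsFactors = FALSE
  )
  for (sp in species) {
    rscu_wide[[sp]] <- rscu_tables[[sp]]$rscu[
      match(rscu_wide$codon, rscu_tables[[sp]]$codon)]
  }
  avg <- NULL
  if (length(species) >= 2L) {
    avg <- average_rscu(rscu_tables, mode = "mean")
    rscu_wide$average <- avg$rscu[match(rscu_wide$codon, avg$codon)]
  }
  note("rscu", .emit(rscu_wide, "rscu", config$out_dir, rounding))
  if (length(species) >= 2L) {
    cl <- rscu_cluster(rscu_tables)
    writeLines(c(paste("codon_order:", paste(cl$codon_order, collapse = ",")),
                 paste("species_order:",
                       paste(cl$species_order, collapse = ","))),
               file.path(config$out_dir, "rscu_cluster.txt"))
    note("rscu_cluster", file.path(config$out_dir, "rscu_cluster.txt"))
  }

  refs <- lapply(config$reference_tables, function(r) {
    if (inherits(r, "ref_usage")) r else read_reference_usage(r)
  })
  indices <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    cc <- count_codons(cds$bases[i], include_stops = FALSE)
    e <- enc(cc)
    cai_val <- if (!is.null(refs[[cds$species[i]]])) {
      cai(cc, refs[[cds$species[i]]])$cai
    } else NA_real_
    data.frame(id = cds$id[i], species = cds$species[i],
               enc = e$enc, cai = cai_val, stringsAsFactors = FALSE)
  }))
  if (is.null(config$reference_tables)) {
    skipped <- c(skipped, "cai: no reference tables supplied")
  }
  note("indices", .emit(indices, "indices", config$out_dir, rounding))

  p2_rows <- do.call(rbind, lapply(species, function(sp) {
    r <- p2(rscu_tables[[sp]], mode = config$p2_mode)
    data.frame(species = sp, SSU = r$sSU, WWU = r$wWU, SSC = r$sSC,
               WWC = r$wWC, P2 = r$p2, stringsAsFactors = FALSE)
  }))
  note("p2", .emit(p2_rows, "p2", config$out_dir, rounding))

  neut <- neutrality(profiles)
  neut_df <- data.frame(slope = neut$slope, intercept = neut$intercept,
                        pearson_r = neut$pearson_r, p_value = neut$p_value,
                        n = neut$n, mutation_pct = neut$mutation_pct,
                        selection_pct = neut$selection_pct)
  note("neutrality", .emit(neut_df, "neutrality", config$out_dir, rounding))

  pr2_res <- pr2(profiles)
  note("pr2", .emit(pr2_res$per_sequence, "pr2", config$out_dir, rounding))

  eg <- enc_gc3_points(indices$enc, profiles$gc3 / 100)
  note("enc_gc3", .emit(eg$points, "enc_gc3", config$out_dir, rounding))

  feats <- cbind(profiles[, c("pct_A", "pct_T", "pct_G", "pct_C",
                              "pct_A3", "pct_T3", "pct_G3", "pct_C3",
                              "gc3")],
                 enc = indices$enc)
  if (!all(is.na(indices$cai))) feats$cai <- indices$cai
  ct <- correlation_table(feats)
  corr_df <- data.frame(pair = character(0), r = numeric(0),
                        p = numeric(0), stars = character(0))
  nm <- rownames(ct$r)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      corr_df <- rbind(corr_df, data.frame(
        pair = paste(nm[i], nm[j], sep = "~"),
        r = ct$r[i, j], p = ct$p[i, j], stars = ct$stars[i, j],
        stringsAsFactors = FALSE))
    }
  }
  note("correlations",
       .emit(corr_df, "correlations", config$out_dir, rounding))
  note("enc_regressions",
       .emit(enc_regressions(feats), "enc_regressions",
             config$out_dir, rounding))

  if (!is.null(config$trna_tables)) {
    trnas <- lapply(config$trna_tables, function(t) {
      if (inherits(t, "trna_table")) t else read_trna_counts(t)
    })
    adapt <- do.call(rbind, lapply(intersect(species, names(trnas)),
                                   function(sp) {
      rep <- adaptation_report(rscu_tables[[sp]], trnas[[sp]])
      cbind(species = sp, as.data.frame(rep))
    }))
    note("adaptation", .emit(adapt, "adaptation", config$out_dir, rounding))
  } else {
    skipped <- c(skipped, "trna_adaptation: SKIPPED (no tRNA tables)")
  }

  if (!is.null(config$alignment)) {
    aln <- if (is.data.frame(config$alignment)) config$alignment else
      read_cds_fasta(config$alignment)
    if (length(unique(nchar(aln$bases))) > 1L) {
      stop("alignment sequences are not of equal length")
    }
    km <- k2p_matrix(aln)
    utils::write.table(round(km$d, 6), file.path(config$out_dir, "k2p.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    note("k2p", file.path(config$out_dir, "k2p.tsv"))
    if (nrow(km$d) >= 3L) {
      tree <- neighbor_joining(km, quiet = TRUE)
      writeLines(write_newick(tree), file.path(config$out_dir, "tree.nwk"))
      note("tree", file.path(config$out_dir, "tree.nwk"))
    }
  } else {
    skipped <- c(skipped, "phylogeny: SKIPPED (no alignment)")
  }

  structure(
    list(manifest = manifest,
         skipped = skipped,
         summary = list(
           n_sequences = nrow(cds),
           total_codons = sum(cds$codon_count),
           mean_enc = mean(indices$enc),
           mean_cai = if (all(is.na(indices$cai))) NA_real_
                      else mean(indices$cai, na.rm = TRUE),
           neutrality_slope = neut$slope,
           pr2_overall = pr2_res$overall,
           fraction_below_curve = eg$fraction_below_curve),
         profiles = profiles, rscu_tables = rscu_tables,
         indices = indices, p2 = p2_rows, neutrality = neut),
    class = "analysis_bundle"
  )
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Codon-usage analysis bundle:", length(x$manifest), "tables in",
      dirname(x$manifest[[1]]), "\n")
  cat(sprintf("  %d sequences, %d codons; mean ENc %.2f; slope %.3f\n",
              x$summary$n_sequences, x$summary$total_codons,
              x$summary$mean_enc, x$summary$neutrality_slope))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "),
                             "\n")
  invisible(x)
}
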