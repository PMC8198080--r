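# Reading and validating coding sequences, codon counting, and parsers for
# the two sidecar table formats: Kazusa-style "countcodon" reference usage
# tables and tRNA gene-count tables (amino acid -> anticodon isotypes).

#' Read coding sequences from a multi-FASTA file
#'
#' Records are normalized to the DNA alphabet (U -> T, upper case) and the
#' original header line is kept as the record id. Species labels come from
#' the `species` argument, not from free-text headers.
#'
#' @param path Path to a FASTA file.
#' @param species Species label applied to every record (recycled), or a
#'   character vector with one label per record.
#' @return A data frame with columns `id`, `species`, `bases`, `codon_count`.
#' @export
read_cds_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file contains no records: ", path)
  bases <- .to_dna(as.character(recs))
  cds_set(id = names(recs), bases = unname(bases), species = species)
}

#' Assemble a coding-sequence set from raw strings
#'
#' @param id Record identifiers.
#' @param bases Nucleotide strings (U is normalized to T, case folded).
#' @param species Species labels, recycled to length.
#' @return A data frame with columns `id`, `species`, `bases`, `codon_count`.
#' @export
cds_set <- function(id, bases, species = NA_character_) {
  bases <- .to_dna(bases)
  data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), length(bases)),
    bases = bases,
    codon_count = nchar(bases) %/% 3L,
    stringsAsFactors = FALSE
  )
}

#' Validate a coding sequence
#'
#' A CDS passes when its length is a positive multiple of three, it begins
#' with ATG, ends with a stop codon, contains no internal stop and no
#' character outside A, C, G, T. All problems are reported, none raised.
#'
#' @param bases A single nucleotide string (DNA or RNA alphabet).
#' @return List with `passed` (logical) and `failures` (character vector of
#'   reason codes among `BAD_LENGTH`, `NO_START`, `NO_TERMINAL_STOP`,
#'   `INTERNAL_STOP`, `AMBIGUOUS_BASE`).
#' @export
validate_cds <- function(bases) {
  stopifnot(length(bases) == 1L)
  b <- .to_dna(bases)
  failures <- character(0)
  n <- nchar(b)
  if (n == 0L || n %% 3L != 0L) failures <- c(failures, "BAD_LENGTH")
  if (grepl("[^ACGT]", b)) failures <- c(failures, "AMBIGUOUS_BASE")
  if (n >= 3L && n %% 3L == 0L) {
    cods <- codon_split(b)
    if (cods[1L] != START_CODON) failures <- c(failures, "NO_START")
    if (!cods[length(cods)] %in% STOP_CODONS) {
      failures <- c(failures, "NO_TERMINAL_STOP")
    }
    if (length(cods) > 1L &&
        any(cods[-length(cods)] %in% STOP_CODONS)) {
      failures <- c(failures, "INTERNAL_STOP")
    }
  } else if (n >= 3L) {
    # frame is broken; still check the start and the trailing bases
    if (substr(b, 1L, 3L) != START_CODON) failures <- c(failures, "NO_START")
    if (!substr(b, n - 2L, n) %in% STOP_CODONS) {
      failures <- c(failures, "NO_TERMINAL_STOP")
    }
  } else {
    failures <- c(failures, "NO_START", "NO_TERMINAL_STOP")
  }
  list(passed = length(failures) == 0L, failures = failures)
}

#' Validate every record of a coding-sequence set
#'
#' @param cds A data frame as returned by [read_cds_fasta()].
#' @return A data frame with columns `id`, `passed`, `failures`
#'   (semicolon-separated reason codes).
#' @export
validate_cds_set <- function(cds) {
  reports <- lapply(cds$bases, validate_cds)
  data.frame(
    id = cds$id,
    passed = vapply(reports, `[[`, logical(1), "passed"),
    failures = vapply(reports, function(r) paste(r$failures, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Drop invalid records from a coding-sequence set
#'
#' Advisory by default: failing records are excluded with a message. With
#' `strict = TRUE` any failure aborts.
#'
#' @param cds A coding-sequence set.
#' @param strict Abort on the first invalid record instead of excluding it.
#' @param quiet Suppress the per-record exclusion messages.
#' @return The subset of `cds` that passes validation.
#' @export
filter_valid_cds <- function(cds, strict = FALSE, quiet = FALSE) {
  rep <- validate_cds_set(cds)
  if (strict && any(!rep$passed)) {
    bad <- rep[!rep$passed, ]
    stop("invalid CDS record(s): ",
         paste0(bad$id, " [", bad$failures, "]", collapse = ", "))
  }
  if (!quiet && any(!rep$passed)) {
    bad <- rep[!rep$passed, ]
    message("excluding ", nrow(bad), " record(s): ",
            paste0(bad$id, " [", bad$failures, "]", collapse = ", "))
  }
  cds[rep$passed, , drop = FALSE]
}

#' Split a nucleotide string into codons
#' @param bases A single string whose length is a multiple of three.
#' @return Character vector of codons.
#' @export
codon_split <- function(bases) {
  b <- .to_dna(bases)
  n <- nchar(b)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(b, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Count codons over a set of coding sequences
#'
#' Counts are pooled across sequences. Stop codons are excluded by default;
#' codon-bias indices are defined over sense codons only.
#'
#' @param x A coding-sequence set data frame, or a character vector of
#'   nucleotide strings.
#' @param include_stops Count the three stop codons as well.
#' @return Object of class `codon_counts`: list with `counts` (named
#'   integer vector over the 64 codons), `total_codons` and `include_stops`.
#' @export
count_codons <- function(x, include_stops = FALSE) {
  bases <- if (is.data.frame(x)) x$bases else .to_dna(x)
  cods <- unlist(lapply(bases, codon_split), use.names = FALSE)
  tab <- table(factor(cods, levels = all_codons()))
  counts <- stats::setNames(as.integer(tab), all_codons())
  if (!include_stops) counts[STOP_CODONS] <- 0L
  codon_count_table(counts, include_stops = include_stops)
}

#' Construct a codon count table from a named count vector
#'
#' @param counts Named non-negative counts; codons not named are zero.
#' @param include_stops Whether stop-codon counts are meaningful.
#' @return Object of class `codon_counts`.
#' @export
codon_count_table <- function(counts, include_stops = FALSE) {
  full <- stats::setNames(integer(64), all_codons())
  nm <- .to_dna(names(counts))
  if (anyDuplicated(nm)) stop("duplicate codon in counts")
  if (!all(nm %in% all_codons())) {
    stop("unknown codon(s): ", paste(setdiff(nm, all_codons()), collapse = ", "))
  }
  if (any(counts < 0)) stop("negative codon count")
  full[nm] <- as.integer(round(counts))
  structure(
    list(counts = full,
         total_codons = sum(full),
         include_stops = include_stops),
    class = "codon_counts"
  )
}

#' Per-family codon totals of a count table
#' @param counts A `codon_counts` object.
#' @return Named integer vector over the 18 degenerate amino acids.
#' @export
family_totals <- function(counts) {
  vapply(synonymous_families(),
         function(cods) sum(counts$counts[cods]), numeric(1))
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon count table:", x$total_codons, "codons",
      if (x$include_stops) "(stops included)" else "(sense codons only)", "\n")
  invisible(x)
}

#' Read a Kazusa-style codon usage reference table
#'
#' The "countcodon" text layout: whitespace-separated triplets of
#' `CODON  frequency-per-thousand  (count)`, in either the DNA or RNA
#' alphabet. All 64 codons must be present exactly once.
#'
#' @param path Path to the table.
#' @param species Optional species label stored with the table.
#' @return Object of class `ref_usage`: data frame with columns `codon`
#'   (DNA alphabet), `freq_per_1000`, `count`.
#' @export
read_reference_usage <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("reference usage table not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  m <- gregexpr("([AaCcGgTtUu]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
                txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1]]
  if (length(hits) == 0L) stop("no codon entries found in ", path)
  parts <- regmatches(hits,
                      regexec("([AaCcGgTtUu]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
                              hits, perl = TRUE))
  codon <- .to_dna(vapply(parts, `[`, character(1), 2L))
  freq <- as.numeric(vapply(parts, `[`, character(1), 3L))
  count <- as.integer(vapply(parts, `[`, character(1), 4L))
  if (anyDuplicated(codon)) {
    stop("duplicate codon in reference table: ",
         paste(unique(codon[duplicated(codon)]), collapse = ", "))
  }
  missing <- setdiff(all_codons(), codon)
  if (length(missing) > 0L) {
    stop("MISSING_CODON: reference table lacks ",
         paste(missing, collapse = ", "))
  }
  df <- data.frame(codon = codon, freq_per_1000 = freq, count = count,
                   stringsAsFactors = FALSE)
  df <- df[match(all_codons(), df$codon), ]
  rownames(df) <- NULL
  structure(df, class = c("ref_usage", "data.frame"), species = species)
}

#' Read a tRNA gene-count table
#'
#' Tab-separated layout, one row per amino acid: a label such as
#' `Ala (A)`, optionally a preferred-codon column, an isotype list such as
#' `AGC (22), GGC (0), CGC (4), TGC (8)` (anticodons, DNA alphabet, 5'->3'),
#' and a stated total. Split counts written `a/b` (as in initiator vs
#' elongator Met) are summed. By default a row whose stated total does not
#' equal the sum of its itemized counts raises an error naming the row;
#' `strict = FALSE` downgrades this to a warning and keeps the itemized sum.
#'
#' @param path Path to the table.
#' @param species Optional species label stored with the table.
#' @param strict Error (default) or warn on total mismatches.
#' @return Object of class `trna_table`: data frame with columns
#'   `amino_acid` (one-letter), `anticodon`, `count`, plus attributes
#'   `species`, `preferred_codon` (named vector, possibly NA) and
#'   `stated_totals`.
#' @export
read_trna_counts <- function(path, species = NA_character_, strict = TRUE) {
  if (!file.exists(path)) stop("tRNA table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  if (grepl("amino", lines[1L], ignore.case = TRUE)) lines <- lines[-1L]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(fields) {
    fields <- trimws(fields)
    if (length(fields) < 3L) stop("tRNA table row has fewer than 3 fields")
    label <- fields[1L]
    aa1 <- sub(".*\\(([A-Z])\\).*", "\\1", label)
    if (identical(aa1, label)) {
      hit <- match(label, AA_THREE)
      if (is.na(hit)) stop("unrecognized amino-acid label: ", label)
      aa1 <- names(AA_THREE)[hit]
    }
    iso_field <- fields[length(fields) - 1L]
    preferred <- if (length(fields) >= 4L) fields[2L] else NA_character_
    total <- suppressWarnings(as.integer(fields[length(fields)]))
    if (is.na(total)) stop("missing total in row ", label)
    items <- regmatches(
      iso_field,
      gregexpr("([ACGTacgt]{3})\\s*\\(([0-9/]+)\\)", iso_field, perl = TRUE)
    )[[1]]
    if (length(items) == 0L) stop("empty isotype list in row ", label)
    anti <- toupper(sub("\\s*\\(.*", "", items))
    cnt <- vapply(items, function(it) {
      v <- sub(".*\\(([0-9/]+)\\).*", "\\1", it)
      sum(as.integer(strsplit(v, "/", fixed = TRUE)[[1]]))
    }, numeric(1), USE.NAMES = FALSE)
    list(aa = aa1, anticodon = anti, count = as.integer(cnt),
         preferred = preferred, total = total, label = label)
  }
  parsed <- lapply(rows, parse_row)
  for (p in parsed) {
    if (sum(p$count) != p$total) {
      msg <- sprintf(
        "tRNA row %s: stated total %d differs from itemized sum %d",
        p$label, p$total, sum(p$count))
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(parsed, function(p) {
    data.frame(amino_acid = p$aa, anticodon = p$anticodon, count = p$count,
               stringsAsFactors = FALSE)
  }))
  preferred <- stats::setNames(
    vapply(parsed, `[[`, character(1), "preferred"),
    vapply(parsed, `[[`, character(1), "aa"))
  totals <- stats::setNames(
    vapply(parsed, `[[`, numeric(1), "total"),
    vapply(parsed, `[[`, character(1), "aa"))
  structure(df, class = c("trna_table", "data.frame"),
            species = species, preferred_codon = preferred,
            stated_totals = totals)
}
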