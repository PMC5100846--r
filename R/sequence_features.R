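# Sequence-derived transcript features: positional GC content, codon
# adaptation index (CAI), normalized translational efficiency (nTE), and
# poly-proline run classification.

#' Construct a validated coding sequence
#'
#' A coding sequence is a nucleotide string over A/C/G/T whose length is a
#' positive multiple of 3. Lowercase input is uppercased; ambiguity codes
#' are rejected.
#'
#' @param gene_id Gene identifier.
#' @param seq Nucleotide string.
#' @return An object of class `coding_sequence` with fields `gene_id`,
#'   `seq`, and `codons` (character vector of in-frame codons).
#' @export
coding_sequence <- function(gene_id, seq) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  reason <- validate_cds_string(seq)
  if (!is.null(reason)) {
    stop(sprintf("invalid coding sequence for '%s': %s", gene_id, reason),
         call. = FALSE)
  }
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
                      seq(3L, nchar(seq), by = 3L))
  structure(list(gene_id = gene_id, seq = seq, codons = codons),
            class = "coding_sequence")
}

# Returns NULL when valid, otherwise a human-readable rejection reason.
validate_cds_string <- function(seq) {
  if (nchar(seq) == 0L) return("empty sequence")
  if (nchar(seq) %% 3L != 0L) return("length not multiple of 3")
  if (grepl("[^ACGT]", seq)) return("contains non-ACGT characters")
  NULL
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons)\n",
              x$gene_id, nchar(x$seq), length(x$codons)))
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Entries violating the coding-sequence invariants (length not a multiple
#' of 3, ambiguous bases) are reported in a rejects table rather than
#' silently dropped.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A list with `records` (list of [coding_sequence()] objects) and
#'   `rejects` (data frame with columns `gene_id`, `reason`).
#' @export
read_coding_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  records <- list()
  rejects <- list()
  for (i in seq_along(seqs)) {
    reason <- validate_cds_string(seqs[[i]])
    if (is.null(reason)) {
      records[[length(records) + 1L]] <- coding_sequence(ids[[i]], seqs[[i]])
    } else {
      rejects[[length(rejects) + 1L]] <-
        data.frame(gene_id = ids[[i]], reason = reason)
    }
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(gene_id = character(), reason = character())
  list(records = records, rejects = rejects)
}

#' Write coding sequences to a FASTA file
#'
#' @param records List of [coding_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coding_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$gene_id), r$seq)))
  writeLines(lines, path)
  invisible(path)
}

#' GC proportion at each codon position
#'
#' Computes the proportion of G or C bases at codon positions 1, 2, and 3
#' over the codons of a coding sequence. The third position (GC3) is the
#' wobble position; stop codons are not decoded by the ribosome at the
#' wobble position, so the terminal stop codon is excluded by default.
#'
#' @param cds A [coding_sequence()].
#' @param include_terminal_stop Include a terminal stop codon in the counts?
#' @return Named numeric vector `c(gc1, gc2, gc3)`, each in \[0, 1\].
#' @export
gc_by_codon_position <- function(cds, include_terminal_stop = FALSE) {
  stopifnot(inherits(cds, "coding_sequence"))
  codons <- cds$codons
  n <- length(codons)
  if (!include_terminal_stop && codons[n] %in% STOP_CODONS) {
    codons <- codons[-n]
  }
  if (length(codons) == 0L) {
    stop("no codons remain after stop-codon exclusion; GC proportions undefined",
         call. = FALSE)
  }
  gc_at <- function(pos) {
    mean(substr(codons, pos, pos) %in% c("G", "C"))
  }
  c(gc1 = gc_at(1L), gc2 = gc_at(2L), gc3 = gc_at(3L))
}

#' Relative-adaptiveness weights from codon counts
#'
#' Converts a codon frequency table into relative-adaptiveness weights w:
#' within each synonymous family, w(codon) = (count + pseudo_count) /
#' max(count + pseudo_count) over the family, so the most-used synonym of
#' each amino acid has w = 1. Weights are undefined for stop codons. A
#' pseudo-count keeps w strictly positive when some codons are unobserved,
#' which in turn keeps CAI strictly positive.
#'
#' @param counts Named non-negative numeric vector of codon frequencies
#'   over (a subset of) the 61 sense codons; codons absent from `counts`
#'   are taken as 0.
#' @param pseudo_count Non-negative pseudo-count added to every codon
#'   before normalization (default 0.5).
#' @return An object of class `codon_usage_table` with fields `counts` and
#'   `w`, both named over all 61 sense codons.
#' @export
relative_adaptiveness <- function(counts, pseudo_count = 0.5) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0)) stop("codon counts must be non-negative", call. = FALSE)
  if (pseudo_count < 0) stop("pseudo_count must be non-negative", call. = FALSE)
  bad <- setdiff(names(counts), sense_codons())
  if (length(bad)) {
    stop("unknown or stop codons in counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- setNames(numeric(61L), sense_codons())
  full[names(counts)] <- counts
  adj <- full + pseudo_count
  w <- full
  for (family in codon_families()) {
    w[family] <- adj[family] / max(adj[family])
  }
  structure(list(counts = full, w = w), class = "codon_usage_table")
}

#' Codon adaptation index of a coding sequence
#'
#' CAI is the geometric mean of relative-adaptiveness weights w over the
#' codons of a transcript. Following the standard convention, stop codons
#' and the codons of single-codon amino acids (ATG for Met, TGG for Trp,
#' whose w is 1 by construction) are excluded from the mean. Computed in
#' log space for numerical stability.
#'
#' @param cds A [coding_sequence()].
#' @param table A `codon_usage_table` from [relative_adaptiveness()].
#' @return CAI score in (0, 1].
#' @export
cai <- function(cds, table) {
  stopifnot(inherits(cds, "coding_sequence"),
            inherits(table, "codon_usage_table"))
  codons <- cds$codons
  codons <- codons[!(codons %in% c(STOP_CODONS, SINGLE_CODON_AA_CODONS))]
  if (length(codons) == 0L) {
    stop("no countable codons for CAI (only stops/Met/Trp present)",
         call. = FALSE)
  }
  w <- table$w[codons]
  if (any(w <= 0)) {
    stop("zero relative-adaptiveness weight encountered; use a positive pseudo_count",
         call. = FALSE)
  }
  exp(mean(log(w)))
}

#' Read a two-column codon weight table
#'
#' Reads tab-separated `codon<TAB>value` tables used for codon usage
#' counts and nTE weights.
#'
#' @param path Path to a TSV file with columns codon and value (no header
#'   required; a header line is detected and skipped).
#' @return Named numeric vector keyed by codon.
#' @export
read_codon_table <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("codon", "value"),
                   stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.numeric(df$value[1])))) df <- df[-1, ]
  setNames(as.numeric(df$value), toupper(df$codon))
}

#' Normalized translational efficiency of a coding sequence
#'
#' nTE weighs each codon by the balance between its usage demand and the
#' supply of cognate tRNAs. Per-transcript aggregation is the arithmetic
#' mean of per-codon weights over sense codons (a geometric-mean option is
#' provided); a terminal stop codon is excluded.
#'
#' @param cds A [coding_sequence()].
#' @param table Named numeric vector of per-codon nTE weights covering all
#'   codons of `cds`.
#' @param aggregate Aggregation rule: "mean" (default) or "geometric".
#' @return Non-negative nTE score.
#' @export
nte_score <- function(cds, table, aggregate = c("mean", "geometric")) {
  stopifnot(inherits(cds, "coding_sequence"), is.numeric(table),
            !is.null(names(table)))
  aggregate <- match.arg(aggregate)
  codons <- cds$codons
  n <- length(codons)
  if (codons[n] %in% STOP_CODONS) codons <- codons[-n]
  missing_codons <- setdiff(unique(codons), names(table))
  if (length(missing_codons)) {
    stop("nTE table missing codon(s): ", paste(missing_codons, collapse = ", "),
         call. = FALSE)
  }
  vals <- table[codons]
  if (aggregate == "mean") mean(vals) else exp(mean(log(vals)))
}

#' Classify a transcript by presence of a poly-proline run
#'
#' Proline slows peptide-bond formation, especially when several prolines
#' are encoded consecutively. A transcript is classified poly-proline if
#' its codon list contains at least `min_run` consecutive proline codons
#' (CCA/CCC/CCG/CCT).
#'
#' @param cds A [coding_sequence()].
#' @param min_run Minimum run length (default 4).
#' @return Logical.
#' @export
polyproline_class <- function(cds, min_run = 4L) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  is_pro <- cds$codons %in% PROLINE_CODONS
  runs <- rle(is_pro)
  any(runs$values & runs$lengths >= min_run)
}

#' Compute the full sequence-feature table
#'
#' Runs all sequence-derived feature computations over a list of coding
#' sequences.
#'
#' @param records List of [coding_sequence()] objects.
#' @param usage_table A `codon_usage_table` for CAI.
#' @param nte_table Named numeric vector of nTE weights.
#' @param include_terminal_stop Passed to [gc_by_codon_position()].
#' @param min_run Passed to [polyproline_class()].
#' @return Data frame with columns gene_id, coding_length, gc1, gc2, gc3,
#'   cai, nte, polyproline.
#' @export
sequence_feature_table <- function(records, usage_table, nte_table,
                                   include_terminal_stop = FALSE,
                                   min_run = 4L) {
  rows <- lapply(records, function(r) {
    gc <- gc_by_codon_position(r, include_terminal_stop)
    data.frame(
      gene_id = r$gene_id,
      coding_length = nchar(r$seq),
      gc1 = gc[["gc1"]], gc2 = gc[["gc2"]], gc3 = gc[["gc3"]],
      cai = cai(r, usage_table),
      nte = nte_score(r, nte_table),
      polyproline = polyproline_class(r, min_run)
    )
  })
  do.call(rbind, rows)
}
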