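#' Expected restriction-fragment pattern for a -765G>C genotype
#'
#' The 228-bp promoter amplicon is cut into 161 + 67 bp fragments when the
#' G allele is present, while the C allele leaves it uncut. GG therefore
#' yields \{161, 67\}, CC yields \{228\}, and GC yields all three bands
#' \{228, 161, 67\}.
#'
#' @param call Genotype, one of `"GG"`, `"GC"`, `"CC"`.
#' @return Sorted integer vector of fragment lengths (bp).
#' @export
#' @examples
#' expected_fragments("GC")
expected_fragments <- function(call) {
  call <- match.arg(call, c("GG", "GC", "CC"))
  switch(call,
         GG = c(67L, 161L),
         CC = 228L,
         GC = c(67L, 161L, 228L))
}

amplicon_bp <- 228L

#' Call a -765G>C genotype from a restriction-fragment pattern
#'
#' Inverts [expected_fragments()]. By default fragment lengths must match
#' exactly; `tolerance` (bp) admits gel-derived sizes, with any ambiguous
#' match treated as a no-call. Cut patterns must conserve the amplicon
#' length (161 + 67 = 228); anything else — including partial-digestion
#' patterns such as \{228, 161\} — is an explicit no-call error, never a
#' silent default.
#'
#' @param pattern Integer vector of observed fragment lengths (bp).
#' @param tolerance Non-negative matching tolerance in bp (default 0).
#' @return List of class `"genotype_call"` with `call` ("GG"/"GC"/"CC")
#'   and `pooled` ("GG"/"C_carrier").
#' @export
#' @examples
#' call_genotype(c(161, 67))$call  # "GG"
call_genotype <- function(pattern, tolerance = 0) {
  pattern <- as.integer(pattern)
  if (length(pattern) == 0L || anyNA(pattern)) {
    stop("no-call: empty or missing fragment pattern", call. = FALSE)
  }
  if (any(pattern <= 0L | pattern > amplicon_bp)) {
    stop("no-call: fragment length outside 1..", amplicon_bp, " bp",
         call. = FALSE)
  }
  stopifnot(length(tolerance) == 1L, tolerance >= 0)
  matches <- function(obs, exp) {
    if (length(obs) != length(exp)) return(FALSE)
    all(abs(sort(obs) - sort(exp)) <= tolerance)
  }
  hits <- c(GG = matches(pattern, expected_fragments("GG")),
            GC = matches(pattern, expected_fragments("GC")),
            CC = matches(pattern, expected_fragments("CC")))
  if (sum(hits) != 1L) {
    stop("no-call: fragment pattern {", paste(sort(pattern), collapse = ", "),
         "} does not match ",
         if (sum(hits) > 1L) "a unique genotype" else "any genotype",
         call. = FALSE)
  }
  call <- names(hits)[hits]
  if (call %in% c("GG", "GC") && tolerance == 0) {
    cut_bands <- sort(pattern)[sort(pattern) < amplicon_bp]
    if (sum(cut_bands) != amplicon_bp) {
      stop("no-call: cut fragments do not sum to the ", amplicon_bp,
           "-bp amplicon", call. = FALSE)
    }
  }
  structure(list(call = call, pooled = pool_c_carriers(call)),
            class = "genotype_call")
}

#' Pool C-allele carriers
#'
#' Because -765CC homozygotes are rare, GC and CC subjects are combined
#' into a single C-carrier group for analysis.
#'
#' @param call Character vector of genotype calls ("GG"/"GC"/"CC");
#'   `NA` propagates.
#' @return Factor with levels `GG`, `C_carrier`.
#' @export
pool_c_carriers <- function(call) {
  call <- as.character(call)
  bad <- !is.na(call) & !call %in% c("GG", "GC", "CC")
  if (any(bad)) stop("invalid genotype call(s)", call. = FALSE)
  factor(ifelse(is.na(call), NA_character_,
                ifelse(call == "GG", "GG", "C_carrier")),
         levels = c("GG", "C_carrier"))
}

#' Genotype and allele frequencies
#'
#' @param calls Character or factor vector of genotype calls
#'   ("GG"/"GC"/"CC"); `NA` dropped (and counted).
#' @return List of class `"genotype_frequencies"`: counts `n_GG`, `n_GC`,
#'   `n_CC`, total `n`, proportions `freq_GG`, `freq_GC`, `freq_CC`,
#'   `allele_C_freq` = (2 n_CC + n_GC) / (2 n), and `n_missing`.
#' @export
#' @examples
#' genotype_frequencies(rep(c("GG", "GC", "CC"), c(184, 102, 17)))
genotype_frequencies <- function(calls) {
  calls <- as.character(calls)
  n_missing <- sum(is.na(calls))
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("no genotype calls supplied", call. = FALSE)
  if (!all(calls %in% c("GG", "GC", "CC"))) {
    stop("invalid genotype call(s)", call. = FALSE)
  }
  n <- length(calls)
  n_GG <- sum(calls == "GG"); n_GC <- sum(calls == "GC")
  n_CC <- sum(calls == "CC")
  structure(list(n_GG = n_GG, n_GC = n_GC, n_CC = n_CC, n = n,
                 freq_GG = n_GG / n, freq_GC = n_GC / n, freq_CC = n_CC / n,
                 allele_C_freq = (2 * n_CC + n_GC) / (2 * n),
                 n_missing = n_missing),
            class = "genotype_frequencies")
}

#' @export
print.genotype_frequencies <- function(x, ...) {
  cat(sprintf("-765G>C genotypes (n = %d):\n", x$n))
  cat(sprintf("  GG %d (%.1f%%)  GC %d (%.1f%%)  CC %d (%.1f%%)\n",
              x$n_GG, 100 * x$freq_GG, x$n_GC, 100 * x$freq_GC,
              x$n_CC, 100 * x$freq_CC))
  cat(sprintf("  allele C frequency: %.4f\n", x$allele_C_freq))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test comparing the observed
#' genotype counts with the p^2, 2pq, q^2 expectations at the allele
#' frequency estimated from the same counts. A monomorphic sample (allele
#' frequency 0 or 1) is in trivial equilibrium: the statistic is defined
#' as 0.
#'
#' @param freqs A [genotype_frequencies()] object, or a genotype call
#'   vector (converted internally).
#' @return List of class `"aid_test"` with `statistic`, `df`, `p_value`,
#'   `test_name`.
#' @export
hwe_chi_square <- function(freqs) {
  if (!inherits(freqs, "genotype_frequencies")) {
    freqs <- genotype_frequencies(freqs)
  }
  q <- freqs$allele_C_freq
  if (q <= 0 || q >= 1) {
    return(aid_test(0, 1L, 1, "Hardy-Weinberg chi-square"))
  }
  p <- 1 - q
  exp_counts <- freqs$n * c(p^2, 2 * p * q, q^2)
  obs <- c(freqs$n_GG, freqs$n_GC, freqs$n_CC)
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  aid_test(stat, 1L, stats::pchisq(stat, df = 1, lower.tail = FALSE),
           "Hardy-Weinberg chi-square")
}

#' Read fragment patterns or genotype calls from TSV
#'
#' Accepts `subject_id<TAB>fragments` with comma-separated bp values, or
#' `subject_id<TAB>genotype` with GG/GC/CC.
#'
#' @param path TSV file with a header line.
#' @param tolerance Passed to [call_genotype()] for fragment input.
#' @return Data frame with `subject_id`, `genotype`, `pooled`, and for
#'   uncallable patterns `genotype = NA` plus the error in `note`.
#' @export
read_fragments <- function(path, tolerance = 0) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab)) {
    stop("fragment TSV needs a 'subject_id' column", call. = FALSE)
  }
  if ("fragments" %in% names(tab)) {
    res <- lapply(strsplit(as.character(tab$fragments), ","), function(fr) {
      tryCatch({
        g <- call_genotype(as.integer(trimws(fr)), tolerance = tolerance)
        list(genotype = g$call, note = NA_character_)
      }, error = function(e) list(genotype = NA_character_,
                                  note = conditionMessage(e)))
    })
    tab$genotype <- vapply(res, `[[`, character(1), "genotype")
    tab$note <- vapply(res, `[[`, character(1), "note")
  } else if (!"genotype" %in% names(tab)) {
    stop("fragment TSV needs a 'fragments' or 'genotype' column",
         call. = FALSE)
  } else {
    bad <- !is.na(tab$genotype) & !tab$genotype %in% c("GG", "GC", "CC")
    if (any(bad)) stop("invalid genotype value(s) in file", call. = FALSE)
    tab$note <- NA_character_
  }
  tab$pooled <- as.character(pool_c_carriers(tab$genotype))
  tab[, c("subject_id", "genotype", "pooled", "note")]
}
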