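#' Load and filter a miRNA-target interaction table
#'
#' Reads the parsed output of a target predictor (columns `mirna_id`,
#' `target_id`, `target_class`, optionally `score` and `energy_kcal_mol`) and
#' applies the binding-energy filter: records are kept when their predicted
#' free energy of duplex formation is at most `energyCutoff` kcal/mol (more
#' negative means stronger binding, so `energy <= -20` keeps the reliable
#' predictions and drops weak ones). Duplicate `(mirna_id, target_id)` keys
#' are collapsed to the record with the lowest (strongest) energy; records
#' without an energy are kept with a warning reporting how many.
#'
#' @param path TSV path.
#' @param energyCutoff maximum free energy retained, kcal/mol (default -20).
#' @return de-duplicated, filtered interaction data.frame.
#' @export
loadInteractions <- function(path, energyCutoff = -20) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  filterInteractions(df, energyCutoff)
}

#' @rdname loadInteractions
#' @param interactions an in-memory interaction data.frame (same columns).
#' @export
filterInteractions <- function(interactions, energyCutoff = -20) {
  need <- c("mirna_id", "target_id", "target_class")
  miss <- setdiff(need, names(interactions))
  if (length(miss))
    stop("interaction table missing columns: ", paste(miss, collapse = ", "))
  if (!all(interactions$target_class %in% c("mRNA", "circRNA")))
    stop("target_class must be mRNA or circRNA")
  clsPerTarget <- vapply(split(interactions$target_class,
                               interactions$target_id),
                         function(x) length(unique(x)), integer(1))
  if (any(clsPerTarget > 1L))
    stop("inconsistent target_class for target id(s): ",
         paste(names(clsPerTarget)[clsPerTarget > 1L], collapse = ", "))
  if (!"energy_kcal_mol" %in% names(interactions))
    interactions$energy_kcal_mol <- NA_real_
  if (!"score" %in% names(interactions))
    interactions$score <- NA_real_
  nNoEnergy <- sum(is.na(interactions$energy_kcal_mol))
  if (nNoEnergy > 0)
    warning(nNoEnergy, " record(s) lack an energy value and were kept")
  keep <- is.na(interactions$energy_kcal_mol) |
    interactions$energy_kcal_mol <= energyCutoff
  df <- interactions[keep, , drop = FALSE]
  # collapse duplicates, keeping the strongest (lowest-energy) record
  ord <- order(df$mirna_id, df$target_id,
               ifelse(is.na(df$energy_kcal_mol), Inf, df$energy_kcal_mol))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[c("mirna_id", "target_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an interaction table as TSV
#'
#' @param interactions interaction data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

checkRnaAlphabet <- function(seqs, what) {
  bad <- grepl("[^ACGUTacgut]", seqs)
  if (any(bad))
    stop("invalid ", what, " alphabet in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
}

#' Seed-match target prediction (synthetic stand-in)
#'
#' A deliberately simple predictor for fully synthetic runs: an interaction is
#' emitted when the exact reverse complement of the miRNA seed (nucleotides
#' 2-8, the canonical 7mer-m8 site, with U treated as T) occurs in the target
#' sequence. It is *not* an alignment/thermodynamics predictor; synthetic
#' energies are assigned as `-20 - 2 * (number of seed sites)` kcal/mol so
#' every emitted record passes the -20 kcal/mol filter.
#'
#' @param mirnaSeqs named character vector of miRNA sequences (RNA or DNA
#'   alphabet), 5'→3'.
#' @param targetSeqs named character vector of target sequences.
#' @param targetClass `"mRNA"` or `"circRNA"` for all targets.
#' @return interaction data.frame (possibly empty) with the standard columns.
#' @examples
#' predictTargetsSeedMatch(
#'   c(let7 = "UGAGGUAGUAGGUUGUAUAGUU"),
#'   c(t1 = "AAACUACCUCAAA"), "mRNA")
#' @export
predictTargetsSeedMatch <- function(mirnaSeqs, targetSeqs,
                                    targetClass = c("mRNA", "circRNA")) {
  targetClass <- match.arg(targetClass)
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), score = numeric(),
                      energy_kcal_mol = numeric(), stringsAsFactors = FALSE)
  if (length(mirnaSeqs) == 0L || length(targetSeqs) == 0L) return(empty)
  if (is.null(names(mirnaSeqs)) || is.null(names(targetSeqs)))
    stop("sequences must be named")
  checkRnaAlphabet(mirnaSeqs, "miRNA")
  checkRnaAlphabet(targetSeqs, "target")
  toDNA <- function(x) chartr("Uu", "Tt", toupper(x))
  targets <- Biostrings::DNAStringSet(toDNA(targetSeqs))
  hits <- empty
  for (mi in names(mirnaSeqs)) {
    s <- toDNA(mirnaSeqs[[mi]])
    if (nchar(s) < 8L) next
    seed <- Biostrings::DNAString(substr(s, 2L, 8L))
    site <- Biostrings::reverseComplement(seed)
    cnt <- Biostrings::vcountPattern(site, targets)
    found <- which(cnt > 0L)
    if (length(found))
      hits <- rbind(hits, data.frame(
        mirna_id = mi, target_id = names(targetSeqs)[found],
        target_class = targetClass, score = 140 + 10 * cnt[found],
        energy_kcal_mol = -20 - 2 * cnt[found], stringsAsFactors = FALSE))
  }
  rownames(hits) <- NULL
  hits
}
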