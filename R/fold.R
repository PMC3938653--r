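#' @useDynLib mirpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Thermodynamic parameters of the built-in folding engine
#'
#' Returns the nearest-neighbour stacking table (kcal/mol, rows/columns indexed
#' by the closing pair written 5'-base/3'-base: AU, UA, CG, GC, GU, UG) and the
#' loop penalty parameters shared by [fold()] and [duplex()]. The tables ship
#' with the package as plain TSV files under `extdata/`.
#'
#' @return A list with elements `stack` (6x6 numeric matrix) and `params`
#'   (named numeric vector of loop penalties).
#' @export
energy_model <- function() {
  list(stack = get("stack", envir = .mirpipe),
       params = get("loop_params", envir = .mirpipe))
}

# encode an RNA/DNA string as integers 0=A 1=C 2=G 3=U; T is read as U
encode_rna <- function(seq) {
  s <- chartr("acgutT", "ACGUUU", seq)
  v <- utf8ToInt(s)
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 0L
  code[v == utf8ToInt("C")] <- 1L
  code[v == utf8ToInt("G")] <- 2L
  code[v == utf8ToInt("U")] <- 3L
  bad <- !(v %in% utf8ToInt("ACGU"))
  if (any(bad))
    stop("invalid nucleotide(s) in sequence: ",
         paste(unique(strsplit(s, "")[[1]][bad]), collapse = ", "))
  code
}

pairs_to_dotbracket <- function(pairs) {
  db <- rep(".", length(pairs))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  paste(db, collapse = "")
}

gc_percent <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n == 0) return(NA_real_)
  gc <- nchar(gsub("[^GCgc]", "", s))
  100 * gc / n
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Computes the pseudoknot-free minimum free energy (MFE) secondary structure
#' under the package's nearest-neighbour model: stacking energies for adjacent
#' admissible pairs (Watson-Crick and G:U), logarithmic hairpin/bulge/internal
#' loop penalties, and a linear multiloop cost. Hairpin loops span at least
#' 3 nt. Folding is deterministic; ties resolve to the 5'-most pairing.
#'
#' @param seq RNA (or DNA; T read as U) string, alphabet ACGU(T).
#' @return An object of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `pairs` (1-based partner table, 0 = unpaired), `mfe`
#'   (kcal/mol), `amfe` (-MFE per 100 nt), `gc_percent`, and `mfei`
#'   (AMFE / GC%; `NA` when GC% is 0).
#' @seealso [mfei()], [duplex()], [energy_model()]
#' @examples
#' fr <- fold("GGGGAAAACCCC")
#' fr$structure
#' fr$mfe
#' @export
fold <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 5)
    stop("sequence too short to fold (need >= 5 nt)")
  em <- energy_model()
  code <- encode_rna(seq)
  res <- fold_cpp(code, em$stack, em$params)
  out <- list(
    sequence   = toupper(chartr("tT", "uU", seq)),
    structure  = pairs_to_dotbracket(res$pairs),
    pairs      = res$pairs,
    mfe        = res$mfe,
    amfe       = -res$mfe / nchar(seq) * 100,
    gc_percent = gc_percent(seq)
  )
  out$mfei <- if (isTRUE(out$gc_percent > 0)) out$amfe / out$gc_percent else NA_real_
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("MFE %.2f kcal/mol | AMFE %.2f | GC %.1f%% | MFEI %s\n",
              x$mfe, x$amfe, x$gc_percent,
              ifelse(is.na(x$mfei), "NA", sprintf("%.3f", x$mfei))))
  invisible(x)
}

#' Minimal free energy index of a folded sequence
#'
#' MFEI = AMFE / GC% with AMFE = -MFE / length x 100 and GC% on the 0-100
#' scale. Values above 0.85 discriminate miRNA precursors from tRNA, rRNA and
#' mRNA fragments.
#'
#' @param fold_result A [fold()] result.
#' @return The dimensionless index; `NA` (flagged undefined) when GC% is 0.
#' @export
mfei <- function(fold_result) {
  stopifnot(inherits(fold_result, "fold_result"))
  if (!isTRUE(fold_result$gc_percent > 0)) return(NA_real_)
  fold_result$amfe / fold_result$gc_percent
}

#' Hybridisation energy of two RNA strands
#'
#' Finds the optimal non-crossing intermolecular pairing between `seq_a` and
#' `seq_b` (antiparallel) under the same nearest-neighbour stack table and
#' loop penalties as [fold()], with no intramolecular structure. The energy of
#' two strands with no admissible pairing is 0; any pairing can only lower it.
#'
#' @param seq_a,seq_b RNA strings, 5' to 3'.
#' @return An object of class `duplex_result`: `seq_a`, `seq_b`, `mfe`
#'   (kcal/mol), and `pairs` (for each position of `seq_a`, the 1-based
#'   partner position in `seq_b`, or 0).
#' @examples
#' duplex("ACGUACGUACGUACGUACGUA", revcomp_rna("ACGUACGUACGUACGUACGUA"))$mfe
#' @export
duplex <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("duplex() requires two non-empty sequences")
  em <- energy_model()
  a <- encode_rna(seq_a)
  b <- encode_rna(seq_b)
  res <- duplex_cpp(a, rev(b), em$stack, em$params)
  prs <- res$pairs
  m <- length(b)
  prs[prs > 0] <- m + 1L - prs[prs > 0] # back to original seq_b coordinates
  structure(list(seq_a = toupper(chartr("tT", "uU", seq_a)),
                 seq_b = toupper(chartr("tT", "uU", seq_b)),
                 mfe = res$mfe, pairs = prs),
            class = "duplex_result")
}

#' Reverse complement in the RNA alphabet
#'
#' @param seq RNA/DNA string; T is read as U.
#' @return The reverse complement, RNA alphabet.
#' @export
revcomp_rna <- function(seq) {
  s <- chartr("acgutTACGU", "UGCAAAUGCA", seq)
  vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

# reverse complement in the DNA alphabet (internal storage alphabet)
revcomp_dna <- function(seq) {
  s <- chartr("ACGTacgt", "TGCATGCA", toupper(seq))
  vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}
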