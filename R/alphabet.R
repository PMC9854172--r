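#' @useDynLib coordesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm cor sd dist setNames
#' @importFrom utils combn head tail modifyList
NULL

#' The 20-letter amino-acid alphabet
#'
#' Fixed alphabetical one-letter order used by every 20-vector and
#' 20x20 matrix in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter, standard 20 plus declared fallbacks
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  MSE = "M", SEC = "C"
)

#' Convert a sequence string to 1..20 integer codes
#'
#' @param seq character scalar over [AA_ALPHABET] or character vector of
#'   single letters.
#' @return integer vector of codes in 1..20.
#' @export
seq_to_int <- function(seq) {
  letters1 <- if (length(seq) == 1L && nchar(seq) > 1L) {
    strsplit(seq, "", fixed = TRUE)[[1]]
  } else {
    as.character(seq)
  }
  idx <- match(letters1, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(letters1[is.na(idx)])
    stop("letters outside the 20-letter alphabet: ", paste(bad, collapse = " "))
  }
  idx
}

#' Convert integer codes back to a sequence string
#'
#' @param codes integer vector in 1..20.
#' @return character scalar.
#' @export
int_to_seq <- function(codes) {
  stopifnot(all(codes >= 1L), all(codes <= 20L))
  paste(AA_ALPHABET[codes], collapse = "")
}
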