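#' American Soundex phonetic code
#'
#' Classic American Soundex: the first letter is retained, remaining
#' consonants map to digit classes (BFPV=1, CGJKQSXZ=2, DT=3, L=4, MN=5,
#' R=6), vowels separate equal codes, and H/W do not (equal codes on either
#' side of H/W collapse). Output is the initial letter plus three digits,
#' zero-padded. Inputs are case-folded and stripped of non-letters first.
#'
#' @param x character vector of names.
#' @param sentinel code returned for empty or non-alphabetic input.
#' @return character vector of 4-character codes.
#' @export
#' @examples
#' soundex(c("Robert", "Tymczak", "Ashcraft"))
soundex <- function(x, sentinel = "0000") {
  vapply(as.character(x), soundex_one, character(1),
    sentinel = sentinel, USE.NAMES = FALSE)
}

.soundex_codes <- local({
  codes <- rep(NA_character_, 26)
  names(codes) <- letters
  codes[c("b", "f", "p", "v")] <- "1"
  codes[c("c", "g", "j", "k", "q", "s", "x", "z")] <- "2"
  codes[c("d", "t")] <- "3"
  codes["l"] <- "4"
  codes[c("m", "n")] <- "5"
  codes["r"] <- "6"
  codes[c("a", "e", "i", "o", "u", "y")] <- "0"
  codes  # h, w stay NA: dropped before collapsing
})

soundex_one <- function(s, sentinel = "0000") {
  if (is.na(s)) return(sentinel)
  ch <- strsplit(tolower(s), "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% letters]
  if (!length(ch)) return(sentinel)
  first <- toupper(ch[1])
  digits <- .soundex_codes[ch]
  digits <- digits[!is.na(digits)]  # remove h/w so codes across them collapse
  if (length(digits)) {
    keep <- c(TRUE, digits[-1] != digits[-length(digits)])
    digits <- digits[keep]
    ## drop the code of the first letter itself (h/w first letters have none)
    if (!ch[1] %in% c("h", "w")) digits <- digits[-1]
    digits <- digits[digits != "0"]
  }
  paste0(first, paste(c(digits, "0", "0", "0")[1:3], collapse = ""))
}
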