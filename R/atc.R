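#' ATC code syntax and level prefixes
#'
#' The WHO Anatomical Therapeutic Chemical classification assigns each
#' drug a 7-character code with five hierarchical levels: one letter
#' (anatomical main group), two digits (therapeutic subgroup), one
#' letter (pharmacological subgroup), one letter (chemical subgroup) and
#' two digits (chemical substance). Truncations at level boundaries
#' (lengths 1, 3, 4, 5, 7) are themselves valid codes; all codes are
#' stored uppercase.
#'
#' @param code character vector of candidate ATC codes.
#' @return \code{validateATC}: logical vector, \code{TRUE} where the
#'   string matches the positional ATC pattern at a legal truncation
#'   length. Total function: malformed input yields \code{FALSE}, never
#'   an error.
#' @examples
#' validateATC(c("N05CB", "L01EM", "5N0CB", "N05CB01"))
#' atcPrefix("L01EM", 3)  # "L01E"
#' @export
validateATC <- function(code) {
  if (length(code) == 0L) return(logical(0))
  code <- toupper(as.character(code))
  patterns <- c(
    "^[A-Z]$",
    "^[A-Z][0-9]{2}$",
    "^[A-Z][0-9]{2}[A-Z]$",
    "^[A-Z][0-9]{2}[A-Z]{2}$",
    "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  )
  out <- rep(FALSE, length(code))
  for (p in patterns) out <- out | grepl(p, code)
  out & !is.na(code)
}

# prefix length of each ATC level
.atc_level_len <- c(1L, 3L, 4L, 5L, 7L)

#' @rdname validateATC
#' @param level integer in 1..5, the hierarchy level of the prefix.
#' @return \code{atcPrefix}: character vector of level-\code{level}
#'   prefixes. Requesting a level deeper than the code carries is an
#'   error.
#' @export
atcPrefix <- function(code, level) {
  stopifnot(length(level) == 1L)
  if (!level %in% 1:5)
    stop("'level' must be an integer in 1..5")
  code <- toupper(as.character(code))
  ok <- validateATC(code)
  if (any(!ok))
    stop("invalid ATC code(s): ",
         paste(utils::head(code[!ok], 5L), collapse = ", "))
  len <- .atc_level_len[level]
  short <- nchar(code) < len
  if (any(short))
    stop("code(s) do not carry level ", level, ": ",
         paste(utils::head(code[short], 5L), collapse = ", "))
  substr(code, 1L, len)
}

#' ATC level-1 anatomical main groups
#'
#' Named character vector mapping the 14 WHO level-1 letters to their
#' group names; used when composing literature-validation queries for a
#' community's label.
#'
#' @examples
#' atcLevel1Names[["L"]]
#' @export
atcLevel1Names <- c(
  A = "Alimentary tract and metabolism",
  B = "Blood and blood forming organs",
  C = "Cardiovascular system",
  D = "Dermatologicals",
  G = "Genito-urinary system and sex hormones",
  H = "Systemic hormonal preparations, excluding sex hormones and insulins",
  J = "Antiinfectives for systemic use",
  L = "Antineoplastic and immunomodulating agents",
  M = "Musculo-skeletal system",
  N = "Nervous system",
  P = "Antiparasitic products, insecticides and repellents",
  R = "Respiratory system",
  S = "Sensory organs",
  V = "Various"
)
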