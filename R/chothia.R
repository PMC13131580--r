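# Chothia site labels.
#
# A site label is a positive integer with an optional single uppercase
# insertion letter, e.g. "52" or "52A".  Labels are kept as character strings
# throughout; the helpers below parse, render and order them.  Ordering is by
# number first, then insertion with "no insertion" < "A" < "B" < ... (the
# conventional Chothia order, so 52 < 52A < 52B < 53).

#' Parse Chothia site labels
#'
#' @param sites character vector of labels such as `"52"` or `"52A"`.
#' @return data.frame with columns `site`, `number` (integer) and `insertion`
#'   (`NA` or a single uppercase letter).
#' @examples
#' chothia_parse(c("52", "52A", "100B"))
#' @export
chothia_parse <- function(sites) {
  sites <- as.character(sites)
  ok <- grepl("^[0-9]+[A-Z]?$", sites)
  if (any(!ok)) {
    stop("malformed Chothia site label(s): ",
         paste(unique(sites[!ok]), collapse = ", "))
  }
  number <- as.integer(sub("[A-Z]$", "", sites))
  if (any(number <= 0L)) stop("Chothia site numbers must be positive")
  insertion <- sub("^[0-9]+", "", sites)
  insertion[insertion == ""] <- NA_character_
  data.frame(site = sites, number = number, insertion = insertion,
             stringsAsFactors = FALSE)
}

#' Render parsed Chothia sites back to labels
#'
#' @param number integer vector of site numbers.
#' @param insertion character vector of insertion codes (`NA` for none).
#' @return character vector of labels; `chothia_render()` is the inverse of
#'   [chothia_parse()].
#' @export
chothia_render <- function(number, insertion = NA_character_) {
  insertion <- ifelse(is.na(insertion), "", insertion)
  paste0(as.integer(number), insertion)
}

#' Numeric sort key for Chothia site labels
#'
#' Encodes the total order (by number, then insertion, with no insertion
#' first) as a numeric key: `number + match(insertion)/100`.
#'
#' @param sites character vector of labels.
#' @return numeric vector; `order(chothia_key(x))` sorts labels correctly.
#' @export
chothia_key <- function(sites) {
  p <- chothia_parse(sites)
  ins_rank <- ifelse(is.na(p$insertion), 0L, match(p$insertion, LETTERS))
  p$number + ins_rank / 100
}

#' Sort Chothia site labels
#'
#' @param sites character vector of labels.
#' @return `sites` in increasing Chothia order.
#' @export
chothia_sort <- function(sites) {
  sites[order(chothia_key(sites))]
}

#' Compare Chothia site labels
#'
#' @param a,b character vectors of labels (recycled).
#' @return logical vector, `TRUE` where `a` precedes `b` in Chothia order.
#' @export
chothia_lt <- function(a, b) {
  chothia_key(a) < chothia_key(b)
}

#' Test membership of sites in an inclusive Chothia range
#'
#' @param sites character vector of labels.
#' @param range length-2 character vector, inclusive bounds.
#' @return logical vector.
#' @export
chothia_in_range <- function(sites, range) {
  stopifnot(length(range) == 2L)
  k <- chothia_key(sites)
  k >= chothia_key(range[1]) & k <= chothia_key(range[2])
}

#' CDR definition for the heavy chain
#'
#' Bundles the inclusive Chothia ranges of the three CDR loops together with
#' the CDR3 removal window used by the accessibility decomposition (the CDR3
#' range extended by one position on each side, default 95-102, capturing the
#' variable part of the V(D)J junction) and the FR4 range (default 103-113),
#' which is retained during CDR3 removal because FR4 is a conserved framework
#' segment.
#'
#' @param cdr1,cdr2,cdr3 inclusive Chothia ranges (length-2 character).
#' @param cdr3_removal_range removal window; must extend `cdr3` by exactly one
#'   position on each side.
#' @param fr4_range FR4 range; must not overlap `cdr3_removal_range`.
#' @return object of class `cdr_definition`.
#' @examples
#' cdr_definition()
#' @export
cdr_definition <- function(cdr1 = c("26", "32"),
                           cdr2 = c("52", "56"),
                           cdr3 = c("96", "101"),
                           cdr3_removal_range = c("95", "102"),
                           fr4_range = c("103", "113")) {
  for (r in list(cdr1, cdr2, cdr3, cdr3_removal_range, fr4_range)) {
    stopifnot(length(r) == 2L)
    if (chothia_lt(r[2], r[1])) stop("range bounds out of order")
  }
  p3 <- chothia_parse(cdr3)
  pr <- chothia_parse(cdr3_removal_range)
  if (!(pr$number[1] == p3$number[1] - 1L && pr$number[2] == p3$number[2] + 1L &&
        is.na(pr$insertion[1]) && is.na(pr$insertion[2]))) {
    stop("cdr3_removal_range must extend cdr3 by one position on each side")
  }
  if (chothia_key(fr4_range[1]) <= chothia_key(cdr3_removal_range[2]) &&
      chothia_key(fr4_range[2]) >= chothia_key(cdr3_removal_range[1])) {
    stop("fr4_range must not overlap cdr3_removal_range")
  }
  structure(list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
                 cdr3_removal_range = cdr3_removal_range,
                 fr4_range = fr4_range),
            class = "cdr_definition")
}

#' @export
print.cdr_definition <- function(x, ...) {
  cat("Heavy-chain CDR definition (Chothia numbering)\n")
  cat(sprintf("  CDR1 %s-%s  CDR2 %s-%s  CDR3 %s-%s\n",
              x$cdr1[1], x$cdr1[2], x$cdr2[1], x$cdr2[2], x$cdr3[1], x$cdr3[2]))
  cat(sprintf("  CDR3 removal window %s-%s, FR4 %s-%s\n",
              x$cdr3_removal_range[1], x$cdr3_removal_range[2],
              x$fr4_range[1], x$fr4_range[2]))
  invisible(x)
}
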