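#' Ballesteros-Weinstein numbering scheme
#'
#' A BW scheme maps each transmembrane helix (1-7) to the sequence number of
#' its x.50 anchor residue. Any BW label "h.xx" then resolves to
#' `anchor(h) + (xx - 50)` by pure arithmetic. Positions beyond 7.50 (the
#' helix 8 region) use the same 7.50-offset rule, so e.g. "7.58" is eight
#' residues past the 7.50 anchor.
#'
#' @param anchors integer vector of length 7: sequence numbers of the x.50
#'   anchors for helices 1-7, strictly increasing. The default is the AT1
#'   receptor assignment (N46, D74, R126, W153, P207, P255, P299).
#' @return an object of class `bw_scheme`.
#' @examples
#' sc <- bw_scheme()
#' bw_residue(sc, "3.50")  # 126
#' bw_residue(sc, "6.34")  # 239
#' @export
bw_scheme <- function(anchors = c(46L, 74L, 126L, 153L, 207L, 255L, 299L)) {
  anchors <- as.integer(anchors)
  if (length(anchors) != 7L || anyNA(anchors))
    stop("a BW scheme needs exactly seven anchor residues (helices 1-7)")
  if (any(diff(anchors) <= 0L))
    stop("BW anchor sequence numbers must be strictly increasing with helix number")
  structure(list(anchors = anchors), class = "bw_scheme")
}

#' @export
print.bw_scheme <- function(x, ...) {
  cat("Ballesteros-Weinstein scheme; x.50 anchors:\n")
  print(stats::setNames(x$anchors, paste0(1:7, ".50")))
  invisible(x)
}

#' Parse a BW label of the form "h.xx"
#'
#' @param label character scalar such as "3.50" or "7.61".
#' @return list with integer fields `helix` and `position`.
#' @export
parse_bw <- function(label) {
  if (length(label) != 1L || !grepl("^[1-7]\\.[0-9]{2}$", label))
    stop("malformed BW label: ", deparse(label), " (expected \"h.xx\", h in 1-7)")
  parts <- strsplit(label, ".", fixed = TRUE)[[1L]]
  list(helix = as.integer(parts[1L]), position = as.integer(parts[2L]))
}

#' Resolve a BW label to a residue sequence number
#'
#' @param scheme a [bw_scheme()].
#' @param label BW label "h.xx" (character), or a list as from [parse_bw()].
#' @return integer residue sequence number: `anchor(h) + (xx - 50)`.
#' @export
bw_residue <- function(scheme, label) {
  stopifnot(inherits(scheme, "bw_scheme"))
  bw <- if (is.character(label)) parse_bw(label) else label
  if (!is.numeric(bw$helix) || bw$helix < 1 || bw$helix > 7)
    stop("unknown helix number: ", bw$helix)
  scheme$anchors[[bw$helix]] + (as.integer(bw$position) - 50L)
}
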