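#' Construct a region scheme
#'
#' A region scheme is a named partition of the ligand-binding-domain
#' sequence into secondary-structure regions (helices, strands and
#' connecting coils), applied identically to each monomer chain.
#'
#' @param regions data.frame with columns `region`, `first`, `last`
#'   (inclusive author residue numbers), in sequence order.
#' @param chains chains the scheme applies to.
#' @return Object of class `region_scheme`.
#' @export
region_scheme <- function(regions, chains = c("A", "B")) {
  stopifnot(is.data.frame(regions),
            all(c("region", "first", "last") %in% names(regions)))
  if (anyDuplicated(regions$region)) stop("duplicate region names")
  if (any(regions$last < regions$first)) stop("region with last < first")
  if (nrow(regions) > 1) {
    o <- order(regions$first)
    r <- regions[o, ]
    if (any(r$first[-1] != r$last[-nrow(r)] + 1))
      stop("regions must be contiguous and non-overlapping")
  }
  rownames(regions) <- NULL
  structure(list(regions = regions, chains = chains),
            class = "region_scheme")
}

#' The 14-region partition of the receptor ligand-binding domain
#'
#' Returns the standard partition of residues 303-552 into 14 regions:
#' helices H1-H12, the coil between H2 and H3 (`C2-3`) and the beta
#' hairpin (`S1S2`). Loop residues are counted with the preceding helix,
#' and H12 spans residues 532-552.
#'
#' @param chains chains the scheme applies to.
#' @return A [region_scheme] with 14 regions jointly covering 303-552.
#' @export
default_region_scheme <- function(chains = c("A", "B")) {
  regions <- data.frame(
    region = c("H1", "H2", "C2-3", "H3", "H4", "H5", "H6", "S1S2",
               "H7", "H8", "H9", "H10", "H11", "H12"),
    first  = c(303, 312, 323, 339, 364, 372, 383, 397,
               412, 420, 440, 464, 495, 532),
    last   = c(311, 322, 338, 363, 371, 382, 396, 411,
               419, 439, 463, 494, 531, 552),
    stringsAsFactors = FALSE
  )
  region_scheme(regions, chains = chains)
}

#' Residue numbers belonging to a named region
#' @param scheme a [region_scheme].
#' @param name region name.
#' @return Integer vector of residue numbers (inclusive range).
#' @export
region_residues <- function(scheme, name) {
  stopifnot(inherits(scheme, "region_scheme"))
  i <- match(name, scheme$regions$region)
  if (is.na(i)) stop("unknown region '", name, "'; available: ",
                     paste(scheme$regions$region, collapse = ", "))
  seq(scheme$regions$first[i], scheme$regions$last[i])
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("<region_scheme> ", nrow(x$regions), " regions covering ",
      min(x$regions$first), "-", max(x$regions$last), " on chains ",
      paste(x$chains, collapse = ","), "\n", sep = "")
  print(x$regions, row.names = FALSE)
  invisible(x)
}
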