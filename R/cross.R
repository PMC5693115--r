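#' Specify a multi-locus genetic cross
#'
#' Describes the parents of a cross as per-locus allele transmission
#' distributions, plus a target offspring genotype, so the expected
#' frequency of that genotype can be computed exactly by enumeration
#' (independent loci, no linkage).
#'
#' Each locus is a list with elements `mother` and `father`; each parent
#' is either a genotype string like `"+/-"` (the two alleles, transmitted
#' with probability 1/2 each) or a named numeric transmission distribution
#' like `c(CRE = 0.5, "+" = 0.5)` summing to 1. The target is a named list
#' mapping locus names to the allowed unordered offspring genotypes,
#' written `"a/b"` with alleles sorted alphabetically (loci omitted from
#' the target accept any genotype).
#'
#' @param loci Named list of loci as described above.
#' @param target Named list of allowed genotypes per locus.
#' @return A `rib_cross` object.
#' @examples
#' # heterozygote intercross at one locus, homozygous-null offspring: 1/4
#' cx <- cross_spec(list(Shh = list(mother = "+/-", father = "+/-")),
#'                  target = list(Shh = "-/-"))
#' expected_genotype_frequency(cx)
#' @export
cross_spec <- function(loci, target) {
  stopifnot(is.list(loci), length(loci) > 0, !is.null(names(loci)),
            is.list(target))
  loci <- lapply(loci, function(locus) {
    stopifnot(is.list(locus), all(c("mother", "father") %in% names(locus)))
    lapply(locus[c("mother", "father")], parse_transmission)
  })
  unknown <- setdiff(names(target), names(loci))
  if (length(unknown) > 0) {
    stop("target references unknown locus/loci: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(loci = loci, target = target), class = "rib_cross")
}

# a genotype string "a/b" -> transmission c(a = .5, b = .5) (exact halves);
# a named numeric is used as-is after checking it sums to 1
parse_transmission <- function(tr) {
  if (is.character(tr) && length(tr) == 1) {
    alleles <- strsplit(tr, "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2) stop("genotype string must be 'a/b': ", tr)
    p <- c(0.5, 0.5)
    names(p) <- alleles
    return(tapply(p, names(p), sum))  # homozygotes collapse to prob 1
  }
  if (is.numeric(tr) && !is.null(names(tr))) {
    if (abs(sum(tr) - 1) > 1e-12) {
      stop("transmission probabilities must sum to 1")
    }
    if (any(tr < 0)) stop("transmission probabilities must be >= 0")
    return(tr[tr > 0])
  }
  stop("each parent must be a genotype string or a named probability vector")
}

genotype_label <- function(a1, a2) {
  # radix sort: byte order, independent of the session locale
  paste(sort(c(a1, a2), method = "radix"), collapse = "/")
}

# offspring genotype distribution at one locus
locus_distribution <- function(locus) {
  probs <- list()
  for (am in names(locus$mother)) {
    for (af in names(locus$father)) {
      g <- genotype_label(am, af)
      p <- locus$mother[[am]] * locus$father[[af]]
      probs[[g]] <- (if (is.null(probs[[g]])) 0 else probs[[g]]) + p
    }
  }
  unlist(probs)
}

#' Joint offspring genotype distribution of a cross
#'
#' @param cross A [cross_spec()] object.
#' @return A data.frame with one column per locus (offspring genotype,
#'   unordered `"a/b"` labels) and a `prob` column; probabilities sum
#'   to 1.
#' @export
genotype_distribution <- function(cross) {
  stopifnot(inherits(cross, "rib_cross"))
  dists <- lapply(cross$loci, locus_distribution)
  grid <- expand.grid(lapply(dists, names),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(cross$loci)
  prob <- rep(1, nrow(grid))
  for (locus in names(dists)) {
    prob <- prob * unname(dists[[locus]][grid[[locus]]])
  }
  grid$prob <- prob
  grid
}

#' Expected offspring frequency of a target genotype
#'
#' Enumerates all per-locus transmission outcomes of a [cross_spec()] and
#' sums the probabilities of joint genotypes matching the target. With
#' rational transmission probabilities (halves, as in Mendelian
#' segregation) the arithmetic is exact.
#'
#' @param cross A [cross_spec()] object.
#' @return The exact probability.
#' @examples
#' expected_genotype_frequency(cross_shh_apaf1_dko())   # 1/8
#' expected_genotype_frequency(cross_shh_casp3_dko())   # 1/16
#' @export
expected_genotype_frequency <- function(cross) {
  dist <- genotype_distribution(cross)
  match <- rep(TRUE, nrow(dist))
  for (locus in names(cross$target)) {
    match <- match & dist[[locus]] %in% cross$target[[locus]]
  }
  sum(dist$prob[match])
}

#' The Shh;Apaf1 double-knockout cross
#'
#' Mother `Apaf1(+/-); Shh(fl/fl)`, father carrying a ubiquitous CRE
#' deleter and `Apaf1(+/-); Shh(+/-)`. The target DKO offspring is
#' `Apaf1(-/-)` with no functional Shh: the maternal floxed allele plus a
#' paternal null allele, deleted by inherited CRE. With CRE transmitted to
#' all scored offspring (`cre_transmission = 1`, e.g. a homozygous CRE
#' sire) the DKO frequency is 1/8; with `cre_transmission = 0.5`
#' (hemizygous sire) it is 1/16.
#'
#' @param cre_transmission Probability that an offspring inherits the CRE
#'   deleter.
#' @return A `rib_cross` object.
#' @export
cross_shh_apaf1_dko <- function(cre_transmission = 1) {
  stopifnot(cre_transmission >= 0, cre_transmission <= 1)
  cre <- c(CRE = cre_transmission, "+" = 1 - cre_transmission)
  cre <- cre[cre > 0]
  cross_spec(
    loci = list(
      Apaf1 = list(mother = "+/-", father = "+/-"),
      Shh = list(mother = "fl/fl", father = "+/-"),
      CRE = list(mother = c("+" = 1), father = cre)
    ),
    target = list(Apaf1 = "-/-", Shh = "-/fl", CRE = "+/CRE")
  )
}

#' The Shh;Casp3 double-knockout intercross
#'
#' Standard double-heterozygote intercross
#' `Shh(+/-); Casp3(+/-) x Shh(+/-); Casp3(+/-)`; the double-null
#' offspring frequency is 1/16.
#'
#' @return A `rib_cross` object.
#' @export
cross_shh_casp3_dko <- function() {
  cross_spec(
    loci = list(
      Shh = list(mother = "+/-", father = "+/-"),
      Casp3 = list(mother = "+/-", father = "+/-")
    ),
    target = list(Shh = "-/-", Casp3 = "-/-")
  )
}
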