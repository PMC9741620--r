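#' Canonical pedigrees for the standard relationship categories
#'
#' Minimal pedigrees realizing the seven dyadic relationship categories used
#' in the estimator-recovery experiments: parent-offspring, full siblings,
#' half siblings, grandparent-grandchild, uncle-nephew, half uncle - half
#' nephew, and half-first cousins. Each element carries a `dyad` attribute
#' naming the labelled pair and a `theoretical_r` attribute with the exact
#' relatedness (2 x kinship) under non-inbred, mutually unrelated founders.
#'
#' @return A named list of [pedigree()] objects.
#' @export
relationship_pedigrees <- function() {
  peds <- list(
    parent_offspring = list(
      ped = pedigree(c("p1", "p2", "c1"),
                     sire = c(NA, NA, "p1"), dam = c(NA, NA, "p2")),
      dyad = c("p1", "c1"), r = 0.5),
    full_siblings = list(
      ped = pedigree(c("p1", "p2", "c1", "c2"),
                     sire = c(NA, NA, "p1", "p1"),
                     dam = c(NA, NA, "p2", "p2")),
      dyad = c("c1", "c2"), r = 0.5),
    half_siblings = list(
      ped = pedigree(c("p1", "p2", "p3", "c1", "c2"),
                     sire = c(NA, NA, NA, "p1", "p1"),
                     dam = c(NA, NA, NA, "p2", "p3")),
      dyad = c("c1", "c2"), r = 0.25),
    grandparent_grandchild = list(
      ped = pedigree(c("p1", "p2", "p3", "c1", "g1"),
                     sire = c(NA, NA, NA, "p1", "c1"),
                     dam = c(NA, NA, NA, "p2", "p3")),
      dyad = c("p1", "g1"), r = 0.25),
    uncle_nephew = list(
      ped = pedigree(c("p1", "p2", "p3", "u1", "s1", "n1"),
                     sire = c(NA, NA, NA, "p1", "p1", "s1"),
                     dam = c(NA, NA, NA, "p2", "p2", "p3")),
      dyad = c("u1", "n1"), r = 0.25),
    half_uncle_half_nephew = list(
      ped = pedigree(c("p1", "p2", "p3", "p4", "u1", "s1", "n1"),
                     sire = c(NA, NA, NA, NA, "p1", "p1", "s1"),
                     dam = c(NA, NA, NA, NA, "p2", "p3", "p4")),
      dyad = c("u1", "n1"), r = 0.125),
    half_first_cousins = list(
      ped = pedigree(c("p1", "p2", "p3", "p4", "p5", "a1", "b1", "c1", "c2"),
                     sire = c(NA, NA, NA, NA, NA, "p1", "p1", "a1", "b1"),
                     dam = c(NA, NA, NA, NA, NA, "p2", "p3", "p4", "p5")),
      dyad = c("c1", "c2"), r = 0.0625)
  )
  lapply(peds, function(x) {
    ped <- x$ped
    attr(ped, "dyad") <- x$dyad
    attr(ped, "theoretical_r") <- x$r
    ped
  })
}

#' Canonical pedigrees for inbred-offspring categories
#'
#' Minimal pedigrees whose focal member is the offspring of parents with a
#' given relationship: unrelated, full siblings, half siblings, half-first
#' cousins. Each element carries a `target` attribute naming the inbred
#' offspring and a `theoretical_f` attribute with its exact inbreeding
#' coefficient under non-inbred founders.
#'
#' @return A named list of [pedigree()] objects.
#' @export
inbreeding_pedigrees <- function() {
  rel <- relationship_pedigrees()
  add_child <- function(ped, parents, child = "x1") {
    pedigree(c(ped$id, child),
             sire = c(ped$sire, parents[1]),
             dam = c(ped$dam, parents[2]),
             founder_f = c(ifelse(is.na(ped$founder_f), 0, ped$founder_f), 0))
  }
  peds <- list(
    none = list(
      ped = pedigree(c("p1", "p2", "x1"),
                     sire = c(NA, NA, "p1"), dam = c(NA, NA, "p2")),
      f = 0),
    full_siblings = list(
      ped = add_child(rel$full_siblings, c("c1", "c2")), f = 0.25),
    half_siblings = list(
      ped = add_child(rel$half_siblings, c("c1", "c2")), f = 0.125),
    half_first_cousins = list(
      ped = add_child(rel$half_first_cousins, c("c1", "c2")), f = 0.03125)
  )
  lapply(peds, function(x) {
    ped <- x$ped
    attr(ped, "target") <- "x1"
    attr(ped, "theoretical_f") <- x$f
    ped
  })
}
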