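#' Construct a pedigree model
#'
#' A pedigree model is a fixed family structure ending in one inbred mating
#' whose offspring (the focal individual) is the target of the gene-dropping
#' simulation. Members must be listed so that parents precede children;
#' every non-founder has exactly one male and one female parent; founders
#' are mutually unrelated by construction.
#'
#' @param model_id Identifier string.
#' @param class Relationship class of the inbred mating (e.g.
#'   `"uncle_niece"`).
#' @param members A data.frame with columns `id`, `sex` (`"M"`/`"F"`),
#'   `father`, `mother` (`NA` for founders).
#' @param focal `id` of the focal individual.
#' @return A list of class `pedigree_model`.
#' @export
pedigree_model <- function(model_id, class, members, focal) {
  stopifnot(all(c("id", "sex", "father", "mother") %in% names(members)))
  members$id <- as.character(members$id)
  if (anyDuplicated(members$id)) stop("member ids must be unique")
  if (!all(members$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  is_founder <- is.na(members$father) & is.na(members$mother)
  if (any(is.na(members$father) != is.na(members$mother))) {
    stop("each member has either two parents or none")
  }
  for (i in which(!is_founder)) {
    fi <- match(members$father[i], members$id)
    mi <- match(members$mother[i], members$id)
    if (is.na(fi) || is.na(mi)) stop("parent not in member list")
    if (fi >= i || mi >= i) {
      stop("members must be listed in topological order (parents first); cyclic parent maps are impossible under this ordering")
    }
    if (members$sex[fi] != "M") stop("father must be male")
    if (members$sex[mi] != "F") stop("mother must be female")
  }
  if (!focal %in% members$id) stop("focal individual not in member list")
  if (is_founder[match(focal, members$id)]) {
    stop("focal individual must be the offspring of the inbred mating")
  }
  structure(list(model_id = model_id, class = class, members = members,
                 focal = focal),
            class = "pedigree_model")
}

#' @export
print.pedigree_model <- function(x, ...) {
  cat(sprintf("<pedigree_model> %s (%s): %d members, focal = %s\n",
              x$model_id, x$class, nrow(x$members), x$focal))
  invisible(x)
}

ped_df <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(id = m[, 1], sex = m[, 2],
             father = ifelse(m[, 3] == "-", NA, m[, 3]),
             mother = ifelse(m[, 4] == "-", NA, m[, 4]),
             stringsAsFactors = FALSE)
}

#' The ten inbred pedigree models
#'
#' Five relationship classes for the focal individual's parents —
#' half-siblings, uncle–niece, aunt–nephew, grandfather–granddaughter and
#' grandmother–grandson — each in two sex configurations (which parent is
#' shared, or through which sex the generational link passes), giving ten
#' models. Every model yields an expected inbreeding coefficient of
#' F = 0.125 in the focal individual; the configurations differ in their mix
#' of male and female meioses and hence in segment-length distributions.
#' Avuncular links use full siblings (half-avuncular pairs would give
#' F = 0.0625, outside this model family).
#'
#' The registry is plain data: alternative configurations can be built with
#' [pedigree_model()] and used everywhere a registry model is.
#'
#' @return A named list of [pedigree_model()] objects.
#' @export
pedigree_models <- function() {
  models <- list(
    # shared-father half-siblings
    pedigree_model("half_sib_pat", "half_sib", ped_df(
      "GF", "M", "-", "-",
      "GM1", "F", "-", "-",
      "GM2", "F", "-", "-",
      "S", "M", "GF", "GM1",
      "D", "F", "GF", "GM2",
      "X", "M", "S", "D"), "X"),
    # shared-mother half-siblings
    pedigree_model("half_sib_mat", "half_sib", ped_df(
      "GM", "F", "-", "-",
      "GF1", "M", "-", "-",
      "GF2", "M", "-", "-",
      "S", "M", "GF1", "GM",
      "D", "F", "GF2", "GM",
      "X", "M", "S", "D"), "X"),
    # uncle is the full brother of the niece's father
    pedigree_model("uncle_niece_pat", "uncle_niece", ped_df(
      "GF", "M", "-", "-",
      "GM", "F", "-", "-",
      "U", "M", "GF", "GM",
      "B", "M", "GF", "GM",
      "W", "F", "-", "-",
      "N", "F", "B", "W",
      "X", "M", "U", "N"), "X"),
    # uncle is the full brother of the niece's mother
    pedigree_model("uncle_niece_mat", "uncle_niece", ped_df(
      "GF", "M", "-", "-",
      "GM", "F", "-", "-",
      "U", "M", "GF", "GM",
      "S", "F", "GF", "GM",
      "H", "M", "-", "-",
      "N", "F", "H", "S",
      "X", "M", "U", "N"), "X"),
    # aunt is the full sister of the nephew's father
    pedigree_model("aunt_nephew_pat", "aunt_nephew", ped_df(
      "GF", "M", "-", "-",
      "GM", "F", "-", "-",
      "A", "F", "GF", "GM",
      "B", "M", "GF", "GM",
      "W", "F", "-", "-",
      "NE", "M", "B", "W",
      "X", "M", "NE", "A"), "X"),
    # aunt is the full sister of the nephew's mother
    pedigree_model("aunt_nephew_mat", "aunt_nephew", ped_df(
      "GF", "M", "-", "-",
      "GM", "F", "-", "-",
      "A", "F", "GF", "GM",
      "S", "F", "GF", "GM",
      "H", "M", "-", "-",
      "NE", "M", "H", "S",
      "X", "M", "NE", "A"), "X"),
    # grandfather x granddaughter, link through a son
    pedigree_model("grandfather_granddaughter_pat",
                   "grandfather_granddaughter", ped_df(
      "GF", "M", "-", "-",
      "GM1", "F", "-", "-",
      "C", "M", "GF", "GM1",
      "W", "F", "-", "-",
      "GD", "F", "C", "W",
      "X", "M", "GF", "GD"), "X"),
    # grandfather x granddaughter, link through a daughter
    pedigree_model("grandfather_granddaughter_mat",
                   "grandfather_granddaughter", ped_df(
      "GF", "M", "-", "-",
      "GM1", "F", "-", "-",
      "C", "F", "GF", "GM1",
      "H", "M", "-", "-",
      "GD", "F", "H", "C",
      "X", "M", "GF", "GD"), "X"),
    # grandmother x grandson, link through a son
    pedigree_model("grandmother_grandson_pat", "grandmother_grandson",
                   ped_df(
      "GM", "F", "-", "-",
      "GF1", "M", "-", "-",
      "C", "M", "GF1", "GM",
      "W", "F", "-", "-",
      "GS", "M", "C", "W",
      "X", "M", "GS", "GM"), "X"),
    # grandmother x grandson, link through a daughter
    pedigree_model("grandmother_grandson_mat", "grandmother_grandson",
                   ped_df(
      "GM", "F", "-", "-",
      "GF1", "M", "-", "-",
      "C", "F", "GF1", "GM",
      "H", "M", "-", "-",
      "GS", "M", "H", "C",
      "X", "M", "GS", "GM"), "X")
  )
  stats::setNames(models, vapply(models, `[[`, "", "model_id"))
}
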