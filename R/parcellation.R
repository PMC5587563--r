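#' Region parcellation tables
#'
#' A parcellation is a data frame with one row per region and columns
#' `label` (unique region name), `hemisphere` (`"left"` or `"right"`) and
#' `volume` (ROI volume in mm^3, strictly positive). The whole-brain scheme
#' used throughout the package has 72 regions: 33 cortical plus 3
#' subcortical (thalamus, lentiform and caudate nucleus) per hemisphere,
#' ordered alphabetically within hemisphere with the left block first.
#'
#' @param label character vector of unique region names.
#' @param hemisphere character vector, `"left"` or `"right"` per region.
#' @param volume positive numeric vector of region volumes (mm^3).
#' @return A `data.frame` of class `parcellation`.
#' @export
#' @examples
#' p <- parcellation(c("a", "b"), c("left", "right"), c(100, 120))
parcellation <- function(label, hemisphere, volume) {
  label <- as.character(label)
  hemisphere <- as.character(hemisphere)
  volume <- as.numeric(volume)
  if (length(label) != length(hemisphere) || length(label) != length(volume))
    stop("label, hemisphere and volume must have equal length", call. = FALSE)
  if (anyDuplicated(label))
    stop("region labels must be unique", call. = FALSE)
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volumes must be positive and finite", call. = FALSE)
  out <- data.frame(label = label, hemisphere = hemisphere, volume = volume,
                    stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

# The 36 region names of the standard cortical + subcortical scheme
# (33 Desikan-Killiany cortical regions plus thalamus, lentiform and
# caudate nucleus), alphabetical order.
.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "caudate",
  "cuneus", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lentiform", "lingual", "medialorbitofrontal",
  "middletemporal", "parahippocampal", "paracentral", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
  "thalamus", "transversetemporal")

#' Default 72-region whole-brain parcellation
#'
#' Builds the standard 72-region parcellation (36 regions per hemisphere:
#' 33 Desikan-Killiany cortical regions plus thalamus, lentiform and
#' caudate nucleus), left hemisphere block first, regions alphabetical
#' within hemisphere. Labels are prefixed `lh_` / `rh_`.
#'
#' @param volumes optional numeric vector of 72 region volumes (mm^3);
#'   defaults to a constant 5000 mm^3 placeholder.
#' @return A [parcellation] with 72 rows.
#' @export
default_parcellation <- function(volumes = NULL) {
  labels <- c(paste0("lh_", .dk_regions), paste0("rh_", .dk_regions))
  if (is.null(volumes)) volumes <- rep(5000, 72)
  if (length(volumes) != 72)
    stop("volumes must have length 72", call. = FALSE)
  parcellation(labels, rep(c("left", "right"), each = 36), volumes)
}

#' Read a region table from CSV
#'
#' Expects columns `label`, `hemisphere`, `volume`.
#'
#' @param path file path.
#' @return A [parcellation].
#' @export
read_region_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "volume")
  if (!all(need %in% names(d)))
    stop("region table needs columns label, hemisphere, volume", call. = FALSE)
  parcellation(d$label, d$hemisphere, d$volume)
}

#' Write a region table to CSV
#' @param p a [parcellation].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort covariate table from CSV
#'
#' Expects columns `subject_id`, `group` (two levels, e.g. control /
#' patient), `age` (years) and `score` (clinical severity, e.g. YGTSS on a
#' 0-100 scale; may be missing for controls).
#'
#' @param path file path.
#' @return A `data.frame` with the four columns above.
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "score")
  if (!all(need %in% names(d)))
    stop("cohort table needs columns subject_id, group, age, score",
         call. = FALSE)
  if (length(unique(d$group)) != 2)
    stop("cohort table must contain exactly two groups", call. = FALSE)
  d[need]
}
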