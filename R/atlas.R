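# VOI atlas: names of target regions, pseudo-reference candidates, and the
# composite definitions (cortex, EHA) used downstream for PC1 scores.

#' Define a VOI atlas
#'
#' An atlas names the target volumes of interest (VOIs), the candidate
#' pseudo-reference regions, and composite regions built from target VOIs
#' (e.g. whole cortex, or the entorhinal-hippocampus-amygdala "EHA" region).
#' Target and reference sets must be disjoint and composites may only
#' reference defined target VOIs.
#'
#' @param target_vois Character vector of target VOI names.
#' @param reference_candidates Character vector of candidate pseudo-reference
#'   VOI names, disjoint from `target_vois`.
#' @param composites Named list of character vectors; each element defines a
#'   composite region as a subset of `target_vois`.
#' @return An object of class `voi_atlas`.
#' @seealso [default_atlas()]
#' @export
voi_atlas <- function(target_vois, reference_candidates, composites = list()) {
  target_vois <- as.character(target_vois)
  reference_candidates <- as.character(reference_candidates)
  if (anyDuplicated(c(target_vois, reference_candidates))) {
    abort("target and reference VOI names must be unique and disjoint")
  }
  if (!is.list(composites)) abort("`composites` must be a named list")
  for (nm in names(composites)) {
    bad <- setdiff(composites[[nm]], target_vois)
    if (length(bad)) {
      abort(sprintf(
        "composite '%s' references undefined VOIs: %s",
        nm, paste(bad, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      target_vois = target_vois,
      reference_candidates = reference_candidates,
      composites = composites
    ),
    class = "voi_atlas"
  )
}

#' Default mouse-brain VOI atlas
#'
#' Twenty target VOIs (ten neocortical sub-regions split by hemisphere plus
#' ten subcortical regions) and two pseudo-reference candidates (brainstem and
#' periaqueductal gray). Composites: `cortex` (the ten cortical VOIs) and
#' `EHA` (entorhinal cortex, hippocampus, amygdala).
#'
#' @return A `voi_atlas`.
#' @export
default_atlas <- function() {
  cortical <- as.vector(outer(
    c("visual_cortex", "auditory_cortex", "somatosensory_cortex",
      "sensorimotor_cortex", "entorhinal_cortex"),
    c("l", "r"), paste, sep = "_"
  ))
  subcortical <- c(
    "amygdala", "hippocampus", "thalamus", "striatum", "hypothalamus",
    "midbrain", "olfactory_bulb", "cerebellum", "septum", "colliculi"
  )
  voi_atlas(
    target_vois = c(cortical, subcortical),
    reference_candidates = c("brainstem", "periaqueductal_gray"),
    composites = list(
      cortex = cortical,
      EHA = c("entorhinal_cortex_l", "entorhinal_cortex_r",
              "hippocampus", "amygdala")
    )
  )
}

#' @export
print.voi_atlas <- function(x, ...) {
  cat("<voi_atlas>\n")
  cat("  targets:   ", length(x$target_vois), "VOIs\n")
  cat("  references:", paste(x$reference_candidates, collapse = ", "), "\n")
  for (nm in names(x$composites)) {
    cat(sprintf("  composite %-7s %d VOIs\n", paste0(nm, ":"),
                length(x$composites[[nm]])))
  }
  invisible(x)
}
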