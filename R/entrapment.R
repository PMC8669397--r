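# Catenation-parity model of the chromosome entrapment assay: which
# covalently circularized compartments (ring / clamp / frame) retain DNA for
# a given threading topology, and which topologies explain an observed
# retention pattern.

#' ThreadingConfig: DNA crossing counts per compartment
#'
#' A threading topology assigns to each closed DNA component the number of
#' times it passes through the ring and the clamp apertures. The frame
#' compartment is the union of ring and clamp, so its crossing count is the
#' per-component sum and is derived, never stored.
#'
#' @slot name Configuration name.
#' @slot components `data.frame` with columns `component_id`,
#'   `ring_crossings`, `clamp_crossings` (non-negative integers).
#' @slot note Free-text annotation (e.g. geometric caveats).
#' @exportClass ThreadingConfig
setClass("ThreadingConfig",
  representation(name = "character", components = "data.frame",
                 note = "character"))

setValidity("ThreadingConfig", function(object) {
  cm <- object@components
  req <- c("component_id", "ring_crossings", "clamp_crossings")
  if (!all(req %in% names(cm)) || nrow(cm) < 1L)
    return("'components' needs columns component_id, ring_crossings, clamp_crossings")
  if (any(cm$ring_crossings < 0 | cm$clamp_crossings < 0))
    return("crossing counts must be >= 0")
  if (any(cm$ring_crossings != round(cm$ring_crossings)) ||
      any(cm$clamp_crossings != round(cm$clamp_crossings)))
    return("crossing counts must be integers")
  TRUE
})

#' @param name,components,note See the class slots.
#' @rdname ThreadingConfig-class
#' @export
ThreadingConfig <- function(name, components, note = "") {
  new("ThreadingConfig", name = name, components = components, note = note)
}

#' @export
setMethod("show", "ThreadingConfig", function(object) {
  cat(sprintf("ThreadingConfig '%s': %d DNA component(s)\n", object@name,
              nrow(object@components)))
  for (i in seq_len(nrow(object@components)))
    cat(sprintf("  %s: ring %d, clamp %d (frame %d)\n",
                object@components$component_id[i],
                object@components$ring_crossings[i],
                object@components$clamp_crossings[i],
                object@components$ring_crossings[i] +
                  object@components$clamp_crossings[i]))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @rdname ThreadingConfig-class
#' @param x A `ThreadingConfig`.
#' @export
configName <- function(x) x@name

#' Is a closed DNA catenated with a protein circle?
#'
#' A closed DNA is topologically linked with a covalent protein circle iff
#' it crosses any disk spanning the circle an odd number of times; paired
#' in-and-out passes (even counts) are pseudo-topological and separable.
#'
#' @param crossings Non-negative integer crossing count (vectorised).
#' @return Logical.
#' @examples
#' isCatenated(c(0, 1, 2)) # FALSE TRUE FALSE
#' @export
isCatenated <- function(crossings) {
  if (any(crossings < 0)) .stopf("crossing counts must be >= 0")
  crossings %% 2 == 1
}

#' Predict compartment retention for a threading topology
#'
#' A compartment retains DNA in the entrapment assay iff at least one DNA
#' component is catenated with it (odd crossings). The frame uses the
#' per-component sum of ring and clamp crossings.
#'
#' @param config A [ThreadingConfig-class].
#' @return Named logical vector `c(ring =, clamp =, frame =)`.
#' @examples
#' predictRetention(mukbefCandidateConfigs()[["double_lock"]])
#' @export
predictRetention <- function(config) {
  stopifnot(is(config, "ThreadingConfig"))
  cm <- config@components
  c(ring = any(isCatenated(cm$ring_crossings)),
    clamp = any(isCatenated(cm$clamp_crossings)),
    frame = any(isCatenated(cm$ring_crossings + cm$clamp_crossings)))
}

#' Threading topologies consistent with an observed retention pattern
#'
#' @param observed Named logical vector with entries `ring`, `clamp`,
#'   `frame` (the assay outcome).
#' @param candidates List of [ThreadingConfig-class] objects (>= 1).
#' @return The sub-list of candidates whose predicted pattern equals
#'   `observed`, order preserved (possibly empty).
#' @examples
#' consistentConfigs(c(ring = TRUE, clamp = TRUE, frame = FALSE),
#'                   mukbefCandidateConfigs())
#' @export
consistentConfigs <- function(observed, candidates) {
  if (length(candidates) < 1L) .stopf("at least one candidate is required")
  if (!all(c("ring", "clamp", "frame") %in% names(observed)))
    .stopf("'observed' needs named entries ring, clamp, frame")
  obs <- as.logical(observed[c("ring", "clamp", "frame")])
  keep <- vapply(candidates, function(cfg)
    identical(unname(predictRetention(cfg)), obs), logical(1))
  candidates[keep]
}

#' The shipped candidate set of MukBEF threading topologies
#'
#' Encodes the topologies considered for the entrapment experiments:
#' `double_lock` (one loop, one arm in the ring and one in the clamp),
#' `ring_only`, `clamp_only`, `sisters` (two DNA components, one per
#' compartment), `parallel_axis_loop` (loop axis parallel to the ring
#' plane; its enclosed loop tip still catenates the frame),
#' `pseudo_topological` (paired in-and-out passes) and `non_topological`.
#'
#' @return Named list of [ThreadingConfig-class] objects.
#' @export
mukbefCandidateConfigs <- function() {
  one <- function(name, ring, clamp, note = "") {
    ThreadingConfig(name, data.frame(component_id = "loop",
                                     ring_crossings = ring,
                                     clamp_crossings = clamp), note)
  }
  list(
    double_lock = one("double_lock", 1L, 1L,
      "two arms of one loop entrapped separately in ring and clamp"),
    ring_only = one("ring_only", 1L, 0L),
    clamp_only = one("clamp_only", 0L, 1L),
    sisters = ThreadingConfig("sisters",
      data.frame(component_id = c("sister_1", "sister_2"),
                 ring_crossings = c(1L, 0L), clamp_crossings = c(0L, 1L)),
      "sister chromosomes entrapped in different compartments"),
    parallel_axis_loop = one("parallel_axis_loop", 1L, 0L,
      "loop axis parallel to the ring plane; the enclosed loop tip catenates the frame"),
    pseudo_topological = one("pseudo_topological", 2L, 0L,
      "paired in-and-out passes; separable without breaking bonds"),
    non_topological = one("non_topological", 0L, 0L))
}
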