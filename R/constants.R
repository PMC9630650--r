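#' Grasp movement identifiers
#'
#' The four natural grasping movements studied by the pipeline, in the
#' canonical order used throughout: pinch, palmar (whole-hand) grasp,
#' twist, and plug grasp.
#'
#' @return Character vector of length 4.
#' @export
movement_names <- function() c("pinch", "palmar", "twist", "plug")

#' EMG channel labels
#'
#' The eight electrode sites, C1..C8, placed over flexor carpi radialis,
#' extensor digitorum, palmaris longus, brachioradialis, extensor carpi
#' radialis, extensor carpi ulnaris, biceps brachii and triceps brachii.
#'
#' @return Character vector of length 8.
#' @export
channel_names <- function() paste0("C", 1:8)

#' Default maximum voluntary contraction (MVC) per movement
#'
#' Absolute force scale used to convert simulated normalized force to
#' newtons and back. Only the normalized (%MVC) values matter downstream,
#' so these are convenience constants: a strong whole-hand grasp around
#' 100 N, a pinch around 30 N, and torque-type grasps (twist, plug)
#' mapped to equivalent handle forces.
#'
#' @return Named numeric vector (newtons), one entry per movement.
#' @export
default_mvc <- function() {
  c(pinch = 30, palmar = 100, twist = 20, plug = 20)
}

# internal: derive a per-item 32-bit seed from a master seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L)
}
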