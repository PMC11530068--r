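#' Desk-scale benchmark preset and model configuration
#'
#' A scaled-down counterpart of the paper-scale design for single-CPU
#' work: 60 images per homogeneous class, 40 per mixture ratio, rendered
#' directly at 32x32 with 8 cells per scene. Eight cells make every
#' declared ratio realize exactly under largest-remainder rounding
#' (1:2 -> 3+5, 2:1 -> 5+3, 1:3 -> 2+6, 3:1 -> 6+2), so the declared
#' soft label matches the rendered composition, and scenes are crowded
#' enough that cells touch — generation therefore uses
#' `overlap_policy = "allow"`.
#'
#' @return `preset_desk()`: a [generator_preset()].
#' @export
preset_desk <- function() {
  generator_preset(60, 40, RATIO_TAGS,
                   native_size = c(32, 32, 3),
                   canvas_size = c(32, 32, 3),
                   cells_per_image = 8)
}

#' @rdname preset_desk
#' @param seed model seed.
#' @return `model_config_desk()`: a [model_config()] for the tiny_cnn
#'   backbone at 32x32 input — 60 epochs at rate 3e-3 then 1e-3 for the
#'   final third, batch 16. The rate is scaled up from the full-size
#'   schedule because the ~40k-parameter backbone trains from scratch on
#'   a few hundred images; the 2/3-1/3 split of the schedule mirrors the
#'   full-size configuration's early/late structure.
#' @export
model_config_desk <- function(seed = 7L) {
  model_config(backbone = "tiny_cnn", input_size = c(32, 32, 3),
               lr_schedule = list(list(epochs = 1:40, rate = 3e-3),
                                  list(epochs = 41:60, rate = 1e-3)),
               batch_size = 16, epochs = 60, seed = seed,
               average_final_weights = TRUE)
}

#' @rdname preset_desk
#' @return `delta_os_desk()`: per-ratio oversampling increments for the
#'   desk scale — the tuned full-scale pattern (256, 128, 256, 256)
#'   scaled by 1/8 to match the desk training-set size.
#' @export
delta_os_desk <- function() {
  c("1:2" = 32, "2:1" = 16, "1:3" = 32, "3:1" = 32)
}
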