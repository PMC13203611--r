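#' Model configuration
#'
#' Builds the configuration record for a detector variant. The two scales
#' mirror the compact members of the YOLOX family: `tiny` (depth 0.33,
#' width 0.375) and `nano` (depth 0.33, width 0.25, depthwise-separable
#' convolutions). The `backbone` and `neck` fields select the architecture:
#' the dual-stream fusion (DSF) backbone splits features into high- and
#' low-frequency streams with octave cross-fusion after every stage, and the
#' global fusion feedback (GFF) neck replaces the bidirectional PANet-style
#' neck with a single pyramid-pooled global feature fed back to all levels.
#'
#' @param variant one of `"tiny-lite"`, `"nano-lite"`, `"tiny"`, `"nano"`;
#'   the `*-lite` variants use the DSF backbone and GFF neck, the plain ones
#'   the unmodified baseline backbone and neck.
#' @param alpha fraction of channels routed to the low-frequency stream
#'   (dual-stream backbones only). Parameter count is invariant to `alpha`;
#'   FLOPs decrease as `alpha` grows.
#' @param backbone,neck,num_classes,use_depthwise,width,depth overrides of
#'   the variant presets.
#' @return a list of class `sonolite_config`.
#' @export
#' @examples
#' cfg <- model_config("tiny-lite")
#' cfg$width
model_config <- function(variant = c("tiny-lite", "nano-lite", "tiny",
                                     "nano"),
                         alpha = 0.5,
                         backbone = NULL, neck = NULL,
                         num_classes = 1L, use_depthwise = NULL,
                         width = NULL, depth = NULL) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    "tiny"      = list(width = 0.375, depth = 0.33, dw = FALSE,
                       backbone = "baseline", neck = "pafpn"),
    "nano"      = list(width = 0.25, depth = 0.33, dw = TRUE,
                       backbone = "baseline", neck = "pafpn"),
    "tiny-lite" = list(width = 0.375, depth = 0.33, dw = FALSE,
                       backbone = "dsf", neck = "gff"),
    "nano-lite" = list(width = 0.25, depth = 0.33, dw = TRUE,
                       backbone = "dsf", neck = "gff"))
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  cfg <- list(
    variant = variant,
    width = if (is.null(width)) preset$width else width,
    depth = if (is.null(depth)) preset$depth else depth,
    alpha = alpha,
    use_depthwise = if (is.null(use_depthwise)) preset$dw else use_depthwise,
    backbone = if (is.null(backbone)) preset$backbone else backbone,
    neck = if (is.null(neck)) preset$neck else neck,
    num_classes = as.integer(num_classes),
    base_channels = 64L,
    stage_base_channels = c(128L, 256L, 512L, 1024L),
    stage_base_depths = c(3L, 9L, 9L, 3L))
  stopifnot(cfg$backbone %in% c("baseline", "dsf", "nofusion"),
            cfg$neck %in% c("pafpn", "gff"))
  class(cfg) <- "sonolite_config"
  cfg
}

#' @export
print.sonolite_config <- function(x, ...) {
  cat(sprintf(
    "<sonolite_config> %s: width %.3f depth %.2f alpha %.2f %s+%s%s, %d class\n",
    x$variant, x$width, x$depth, x$alpha, x$backbone, x$neck,
    if (x$use_depthwise) " (depthwise)" else "", x$num_classes))
  invisible(x)
}

#' Read / write a model configuration as YAML
#'
#' @param path file path.
#' @param cfg a `sonolite_config`.
#' @return `read_config` returns a `sonolite_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(model_config, y[intersect(names(y),
    c("variant", "alpha", "backbone", "neck", "num_classes",
      "use_depthwise", "width", "depth"))])
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[c("variant", "alpha", "backbone", "neck",
                         "num_classes", "use_depthwise", "width", "depth")],
                   path)
  invisible(path)
}

# derived channel widths
cfg_widths <- function(cfg) {
  bc <- as.integer(floor(cfg$base_channels * cfg$width))
  list(stem = bc,
       stages = as.integer(floor(cfg$stage_base_channels * cfg$width)),
       c3 = as.integer(floor(256 * cfg$width)),
       c4 = as.integer(floor(512 * cfg$width)),
       c5 = as.integer(floor(1024 * cfg$width)),
       head = as.integer(floor(256 * cfg$width)))
}

cfg_depths <- function(cfg) {
  bd <- max(round(3 * cfg$depth), 1)
  as.integer(c(bd, bd * 3L, bd * 3L, bd))
}
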