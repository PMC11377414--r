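# Checkpoint serialization: an RDS container for the weights plus a
# plain-JSON sidecar of the model configuration, so checkpoints are
# self-describing.

.configToList <- function(cfg) {
  list(inChannels = cfg@inChannels, baseWidth = cfg@baseWidth,
       depth = cfg@depth, leakySlope = cfg@leakySlope,
       petOutChannels = cfg@petOutChannels,
       segOutChannels = cfg@segOutChannels, normAffine = cfg@normAffine,
       convFirst = cfg@convFirst, upsample = cfg@upsample)
}

.configFromList <- function(x) {
  modelConfig(inChannels = x$inChannels, baseWidth = x$baseWidth,
              depth = x$depth, leakySlope = x$leakySlope,
              petOutChannels = x$petOutChannels,
              segOutChannels = x$segOutChannels, normAffine = x$normAffine,
              convFirst = x$convFirst, upsample = x$upsample)
}

#' Save / load a training checkpoint
#'
#' `saveCheckpoint()` writes the student and teacher weights with the model
#' configuration and validation score to `path` (RDS) and a JSON sidecar
#' `<path>.json` holding the configuration. `loadCheckpoint()` restores the
#' [Checkpoint-class].
#'
#' @param ckpt a [Checkpoint-class].
#' @param path file path for the checkpoint container.
#' @return `saveCheckpoint`: `path` invisibly; `loadCheckpoint`: the
#'   checkpoint.
#' @export
saveCheckpoint <- function(ckpt, path) {
  cfg <- .configToList(ckpt@model@config)
  saveRDS(list(config = cfg, params = ckpt@model@params,
               teacherParams = ckpt@teacherParams,
               validationScore = ckpt@validationScore,
               epoch = ckpt@epoch), path)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  model <- methods::new("ConnectedUNet", config = .configFromList(x$config),
                        params = x$params)
  methods::new("Checkpoint", model = model,
               teacherParams = x$teacherParams,
               validationScore = x$validationScore, epoch = x$epoch)
}
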