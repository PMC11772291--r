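# Self-describing checkpoint files: config JSON + weight arrays + vocabulary.

#' Save a checkpoint to a JSON file
#'
#' Serialises configuration, vocabulary and all weight arrays at full
#' numeric precision into a single self-describing JSON document.
#'
#' @param ckpt a \code{ner_checkpoint} (or any list with \code{params},
#'   \code{cfg}, \code{vocab_tokens}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
save_checkpoint <- function(ckpt, path) {
  ser <- list(
    cfg = unclass(ckpt$cfg),
    vocab_tokens = ckpt$vocab_tokens,
    variant = ckpt$variant %||% "none",
    params = lapply(ckpt$params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else
        list(dim = NULL, data = as.vector(x))
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path JSON checkpoint path.
#' @return a \code{ner_checkpoint} list.
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(encoder_config, ser$cfg[c("vocab_size", "hidden_dim",
                                           "n_layers", "n_heads", "max_len",
                                           "dropout", "ffn_dim", "seed")])
  params <- lapply(ser$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(p$data, p$dim[1L], p$dim[2L])
    } else {
      as.numeric(p$data)
    }
  })
  structure(list(params = params, cfg = cfg,
                 vocab_tokens = ser$vocab_tokens, variant = ser$variant,
                 log = NULL),
            class = "ner_checkpoint")
}
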