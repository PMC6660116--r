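#' Save / load a fitted model as flat JSON
#'
#' Serializes any fitted classifier (`knn_model`, `ld_model`,
#' `svm_model`, `elm_model`) to a flat JSON document carrying its class,
#' weights, hyperparameters, seeds and node descriptions, so a run can
#' be reproduced or audited without R serialization formats.
#'
#' @param model a fitted model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "ffgf_model"))
    contract_error("write_model expects a fitted ffgf classifier")
  payload <- unclass(model)
  payload$.class <- class(model)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return for `read_model`, the reconstructed model.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) input_error("model file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$.class
  p$.class <- NULL
  if (cls == "knn_model") {
    p$X <- as.matrix(p$X); p$t <- as.numeric(p$t)
  } else if (cls == "elm_model") {
    # simplifyVector collapses the node list to a data.frame; rebuild
    nd <- p$nodes
    p$nodes <- lapply(seq_len(nrow(nd)), function(j)
      list(type = nd$type[j], w = unlist(nd$w[j]), b = nd$b[j]))
    p$B <- as.numeric(p$B)
  }
  structure(p, class = c(cls, "ffgf_model"))
}
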