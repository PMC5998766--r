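# The full-scale configuration used on the licensed DDIExtraction-2013
# corpus, and the published reference results it attains there. The corpus
# is not redistributable, so these numbers are reference values rather than
# gates anything in this package reproduces.

#' Full-scale reference configuration
#'
#' The hyper-parameter set of the published DDI evaluation: maximal length
#' 128, random 300-dimensional word embeddings, 5-dimensional position
#' embeddings, 200 filters for each of the window sizes 2/4/6, mini-batch
#' 50, softmax-weight norm bound 3, dropout 0.5, ReLU non-linearity.
#'
#' @return List with `config` (a [ddi_encoder_config()]) and `control`
#'   (a [ddi_control()]).
#' @export
ddi_reference_config <- function() {
  list(config = ddi_encoder_config(n = 128L, m_e = 300L, m_d = 5L),
       control = ddi_control(batch_size = 50L, dropout = 0.5, l2 = 3,
                             widths = c(2L, 4L, 6L), n_filters = 200L))
}

#' Published reference results on the DDIExtraction-2013 corpus
#'
#' Overall micro-averaged test-set scores reported for this architecture on
#' the licensed DDI corpus, per pooling operator (negative filtering
#' applied except where noted). They require that corpus and full-scale
#' stochastic training, and are recorded here for users who supply the
#' corpus themselves -- they are documentation, not targets this package's
#' synthetic evaluation reproduces.
#'
#' @return Data frame with columns `pooling`, `filtering`, `precision`,
#'   `recall`, `f1` (percentages).
#' @export
ddi_reference_results <- function() {
  data.frame(
    pooling = c("max", "max", "avg", "attentive", "combined"),
    filtering = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    precision = c(67.13, 67.19, 61.70, 64.42, 70.40),
    recall = c(59.22, 62.14, 55.35, 55.14, 59.47),
    f1 = c(62.93, 64.56, 58.35, 59.42, 64.47),
    stringsAsFactors = FALSE)
}
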