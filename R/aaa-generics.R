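# Re-exported tidy/glance/autoplot generics so bmdir results plug into
# broom-style workflows without attaching the generics packages.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
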