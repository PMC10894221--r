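#' Read / write a network configuration as JSON
#'
#' The JSON document has `nodes` (list of `{node_id, r_load, c_parallel,
#' device}`), `coupling` (list of `{i, j, c}` edges), `supply`
#' (`{v_dd, pulse_duration}`), `init` (`{mode, voltages, seed}`) and
#' `integration` (`{dt, record_stride, max_dv_frac}`) blocks. Component
#' values may be SI-suffixed strings (`"8.2k"`, `"100p"`); everything is
#' converted to strict SI on load.
#'
#' @param config An [onn_config()].
#' @param path Optional file path.
#' @return JSON string, or (for `onn_config_from_json`) an `onn_config`.
#' @export
onn_config_to_json <- function(config, path = NULL) {
  n <- length(config$nodes)
  edges <- which(upper.tri(config$coupling) & config$coupling > 0, arr.ind = TRUE)
  x <- list(
    nodes = purrr::map(config$nodes, function(nd)
      list(node_id = nd$node_id, r_load = nd$r_load, c_parallel = nd$c_parallel,
           device = unclass(nd$device))),
    coupling = purrr::map(seq_len(nrow(edges)), function(k)
      list(i = edges[k, 1], j = edges[k, 2], c = config$coupling[edges[k, 1], edges[k, 2]])),
    supply = list(v_dd = config$v_dd, pulse_duration = config$pulse_duration),
    init = list(mode = config$init_mode, voltages = config$init_voltages,
                seed = config$seed),
    integration = list(dt = config$dt, record_stride = config$record_stride,
                       max_dv_frac = config$max_dv_frac))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname onn_config_to_json
#' @param json JSON string or file path.
#' @export
onn_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  nodes <- purrr::map(x$nodes, function(nd)
    oscillator_node(nd$node_id, si_parse(nd$r_load), si_parse(nd$c_parallel),
                    do.call(device_params, nd$device)))
  coupling <- NULL
  if (length(x$coupling)) {
    coupling <- data.frame(i = vapply(x$coupling, `[[`, numeric(1), "i"),
                           j = vapply(x$coupling, `[[`, numeric(1), "j"),
                           c = vapply(x$coupling, function(e) si_parse(e$c), numeric(1)))
  }
  onn_config(nodes, coupling = coupling, v_dd = si_parse(x$supply$v_dd),
             pulse_duration = si_parse(x$supply$pulse_duration),
             init_voltages = x$init$voltages, init_mode = x$init$mode,
             dt = x$integration$dt, record_stride = x$integration$record_stride,
             seed = x$init$seed, max_dv_frac = x$integration$max_dv_frac)
}
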