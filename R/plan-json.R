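#' Read and write the JSON plan fixture dialect
#'
#' Plans are serialized to a small JSON dialect so that synthetic and
#' hand-written fixtures can round-trip losslessly:
#'
#' ```
#' {"plan_id": "...",
#'  "beams": [{"gantry_deg": 0, "beam_mu": 100,
#'             "segments": [{"left_positions": [...],
#'                           "right_positions": [...],
#'                           "mu_weight": 50}, ...]}, ...]}
#' ```
#'
#' Writing uses full double precision (17 significant digits), so write
#' followed by read reproduces every field bit-identically for finite inputs.
#'
#' @param path File path.
#' @return `read_plan_json` returns an [rt_plan()]; `write_plan_json`
#'   invisibly returns `path`.
#' @export
read_plan_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop_imrtqa("plan JSON missing field '", field, "' in ", where)
    obj[[field]]
  }
  plan_id <- need(x, "plan_id", "plan")
  beams_raw <- need(x, "beams", "plan")
  beams <- lapply(seq_along(beams_raw), function(j) {
    b <- beams_raw[[j]]
    where <- paste0("beam ", j)
    segs_raw <- need(b, "segments", where)
    segs <- lapply(seq_along(segs_raw), function(i) {
      s <- segs_raw[[i]]
      sw <- paste0(where, " segment ", i)
      mlc_segment(
        left_positions = as.numeric(unlist(need(s, "left_positions", sw))),
        right_positions = as.numeric(unlist(need(s, "right_positions", sw))),
        mu_weight = as.numeric(need(s, "mu_weight", sw)))
    })
    rt_beam(gantry_deg = as.numeric(need(b, "gantry_deg", where)),
            segments = segs,
            beam_mu = as.numeric(need(b, "beam_mu", where)))
  })
  rt_plan(plan_id = as.character(plan_id), beams = beams)
}

#' @rdname read_plan_json
#' @param plan An [rt_plan()] to serialize.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "rt_plan"))
  x <- list(
    plan_id = plan$plan_id,
    beams = lapply(plan$beams, function(b) {
      list(gantry_deg = b$gantry_deg,
           beam_mu = b$beam_mu,
           segments = lapply(b$segments, function(s) {
             list(left_positions = s$left_positions,
                  right_positions = s$right_positions,
                  mu_weight = s$mu_weight)
           }))
    }))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}
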