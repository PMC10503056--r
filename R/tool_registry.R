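# Risk-tool files and registry.
#
# Tool parameters are data, not code: each tool ships as a YAML file with a
# schema validated on load. The bundled files under extdata/risk_tools are
# synthetic stand-ins (flagged `synthetic: true`) with the structure of the
# published office/lab tool families; users can point the registry at their
# own calibrated files.

#' Load one risk tool from a YAML file
#'
#' Two schemas are supported. `type: equation` files carry one sex-specific
#' proportional-hazards block per outcome (`chd`, `stroke`), each with a
#' baseline 10-year survival `s0` and a predictor list (`name`, `transform`,
#' `beta`, `mean`, optional `lo`/`hi` validity range). `type: chart` files
#' carry age/SBP band edges, an explicit cell table and category midpoints.
#'
#' @param path YAML file path.
#' @return For equations, a list with class `risk_tool_pair` holding
#'   `risk_equation` objects `chd` and `stroke`; for charts, a
#'   [risk_chart()].
#' @export
load_risk_tool <- function(path) {
  if (!file.exists(path)) stop_input("risk tool file not found: ", path)
  spec <- yaml::read_yaml(path)
  for (f in c("tool_id", "mode", "type")) {
    if (is.null(spec[[f]])) stop_input("risk tool file missing field: ", f)
  }
  if (spec$type == "equation") {
    mk_block <- function(b) {
      preds <- do.call(rbind, lapply(b$predictors, function(p) {
        data.frame(name = p$name, transform = p$transform %||% "identity",
                   beta = p$beta, mean = p$mean,
                   lo = p$lo %||% NA_real_, hi = p$hi %||% NA_real_,
                   stringsAsFactors = FALSE)
      }))
      list(s0 = b$s0, predictors = preds)
    }
    mk_eq <- function(outcome) {
      blocks <- spec$outcomes[[outcome]]
      if (is.null(blocks)) stop_input("equation tool missing outcome: ", outcome)
      risk_equation(spec$tool_id, spec$mode, outcome,
                    list(female = mk_block(blocks$female),
                         male = mk_block(blocks$male)))
    }
    structure(list(tool_id = spec$tool_id, mode = spec$mode,
                   chd = mk_eq("chd"), stroke = mk_eq("stroke")),
              class = "risk_tool_pair")
  } else if (spec$type == "chart") {
    cells <- do.call(rbind, lapply(spec$cells, function(cl) {
      data.frame(age_band = cl$a, sbp_band = cl$s, sex = cl$sex,
                 smoker = as.logical(cl$sm), diabetes = as.logical(cl$db),
                 category = cl$cat, stringsAsFactors = FALSE)
    }))
    risk_chart(spec$tool_id, spec$mode,
               age_breaks = unlist(spec$age_breaks),
               sbp_breaks = unlist(spec$sbp_breaks),
               cells = cells,
               category_midpoints = unlist(spec$category_midpoints))
  } else {
    stop_input("unknown risk tool type: ", spec$type)
  }
}

tool_cache <- new.env(parent = emptyenv())

#' Bundled risk-tool set
#'
#' Loads (and caches) the eight bundled synthetic tools: chart-based
#' `who_ish` office/lab and equation-based `who2019`, `framingham`,
#' `globorisk` office/lab. Office equations use BMI where lab equations use
#' total cholesterol.
#'
#' @param dir Directory of tool YAML files; defaults to the files installed
#'   with the package.
#' @return Named list of tools keyed `"<tool_id>_<mode>"`.
#' @export
default_risk_tools <- function(dir = system.file("extdata", "risk_tools",
                                                 package = "cvdscreen")) {
  key <- paste0("dir:", dir)
  if (!is.null(tool_cache[[key]])) return(tool_cache[[key]])
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  if (!length(files)) stop_input("no risk tool files found in ", dir)
  tools <- lapply(files, load_risk_tool)
  names(tools) <- vapply(tools, function(t) paste0(t$tool_id, "_", t$mode),
                         character(1))
  tool_cache[[key]] <- tools
  tools
}

#' Ground-truth annual event probabilities
#'
#' Regardless of which tool a scenario uses for classification, event
#' simulation always uses one designated equation tool (default: the
#' lab-mode WHO-2019-style fixture) to score 10-year CHD and stroke risk,
#' annualised with [annualize_probability()].
#'
#' @param population Population `data.frame`.
#' @param tools Tool registry.
#' @param event_tool Registry key of the ground-truth tool.
#' @return List with `p10_chd`, `p10_stroke`, `p1_chd`, `p1_stroke`.
#' @export
event_risk_probabilities <- function(population, tools = default_risk_tools(),
                                     event_tool = "who2019_lab") {
  tool <- tools[[event_tool]]
  if (is.null(tool) || !inherits(tool, "risk_tool_pair")) {
    stop_input("event tool must be an equation tool pair: ", event_tool)
  }
  p10_chd <- predict_10yr_risk_equation(population, tool$chd)
  p10_stroke <- predict_10yr_risk_equation(population, tool$stroke)
  list(p10_chd = p10_chd, p10_stroke = p10_stroke,
       p1_chd = annualize_probability(p10_chd),
       p1_stroke = annualize_probability(p10_stroke))
}
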