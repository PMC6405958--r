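# Bundled spindle-assembly-checkpoint model hierarchy.
#
# The coarsest network (model3) is four species and three reactions; the
# reduced network (model2) lumps the full model's species into
# Activator/Inhibitor/Promotor classes (7 species, 9 reactions); the full
# network (model1) covers the Mad2/Cdc20/BubR1:Bub3/APC-C machinery (14
# species, 21 reactions).  The "b" variants are the short-timescale
# (pro-metaphase) networks obtained by removing kinetochore attachment
# (and, for the full model, the slow O-Mad2 decay).  The model1 and model2
# reaction lists are reconstructions of the published network diagrams,
# shipped as editable .rn files and validated by their organization counts
# (16/64 and 8/16).

SAC_MODELS <- c("model1", "model1b", "model2", "model2b", "model3", "model3b")

#' Load a bundled SAC model network
#'
#' @param name One of `"model1"`, `"model1b"`, `"model2"`, `"model2b"`,
#'   `"model3"`, `"model3b"`.  The `b` variants are derived from the base
#'   networks by removing the reactions named in the bundled removal
#'   manifest (kinetochore attachment; plus O-Mad2 turnover decay for
#'   `model1b`).
#' @return A `reaction_network`.
#' @examples
#' species(sac_model("model3"))
#' @export
sac_model <- function(name) {
  if (!name %in% SAC_MODELS)
    abort(paste0("unknown model '", name, "'; available: ",
                 paste(SAC_MODELS, collapse = ", ")))
  base <- sub("b$", "", name)
  net <- parse_network(system.file("extdata", paste0(base, ".rn"),
                                   package = "chemorg", mustWork = TRUE),
                       file = TRUE)
  if (endsWith(name, "b")) {
    manifest <- jsonlite::read_json(
      system.file("extdata", "b_variants.json", package = "chemorg",
                  mustWork = TRUE), simplifyVector = TRUE)
    net <- restrict(net, manifest[[name]])
  }
  net
}

# The published "interesting organization" conditions: a meaningful state
# holds a kinetochore (attached or not), an activator in some form, and --
# for the larger models -- the checkpoint machinery in some form.
SAC_PREDICATES <- list(
  model1 = paste(
    "(KinA OR KinU) AND",
    "(Cdc20 OR Cdc20:Mad2 OR MCC OR Cdc20:BubR1:Bub3 OR APC/C:Cdc20 OR",
    " APC/C:MCC OR APC/C:Cdc20:C-Mad2 OR APC/C:Cdc20:BubR1:Bub3) AND",
    "(BubR1:Bub3 OR MCC OR Cdc20:BubR1:Bub3 OR APC/C:MCC OR",
    " APC/C:Cdc20:BubR1:Bub3)"),
  model2 = paste(
    "(KinA OR KinU) AND (Activator OR Inhibitor) AND",
    "(Promotor OR Promotor_A OR Promotor_I)"),
  model3 = "(KinA OR KinU) AND (Activator OR Inhibitor)"
)

#' Interesting-organization predicate presets for the SAC models
#'
#' Returns the boolean species-presence constraint used to single out the
#' biologically meaningful organizations of each model family (the same
#' preset applies to a model and its `b` variant).
#'
#' @param name Model name as in [sac_model()].
#' @return An `org_predicate`.
#' @export
sac_predicate <- function(name) {
  base <- sub("b$", "", name)
  if (!base %in% names(SAC_PREDICATES))
    abort(paste0("no predicate preset for '", name, "'"))
  parse_predicate(SAC_PREDICATES[[base]], sac_model(base))
}

#' Five-compartment path fixture for spatial organization mapping
#'
#' A path of five diffusion-coupled compartments, each holding one
#' kinetochore, in the transition-phase configuration: unattached
#' kinetochores with Inhibitor on one side, attached kinetochores on the
#' other, with the Activator appearing at the far (attached) end.  Used
#' with the short-timescale coarsest network (`model3b`).
#'
#' @return A `compartment_graph`.
#' @export
sac_compartment_fixture <- function() {
  compartment_graph(
    compartments = list(
      `1` = c("Inhibitor", "KinU"),
      `2` = c("Inhibitor", "KinU"),
      `3` = c("Inhibitor", "KinA"),
      `4` = c("Inhibitor", "KinA"),
      `5` = c("Activator", "KinA")
    ),
    edges = cbind(1:4, 2:5),
    net = sac_model("model3b")
  )
}
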