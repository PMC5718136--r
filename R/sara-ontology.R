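# The scaled-down phenotype ontology covering the SARA.
#
# Built programmatically: a cerebellar-phenotype backbone of named classes
# (gait ataxia, truncal ataxia, appendicular ataxia, dysarthria, the
# terminal classes abasia / astasia / anarthria, ...) plus five generated
# severity subclasses for each severity-graded class.  The shipped OBO
# fixture (inst/extdata/sara_phenotype_synthetic.obo) is a synthetic
# reconstruction of the published scaled-down HPO module and matches its
# size: 109 subclasses of the phenotypic-abnormality root.

# backbone: id -> parents (child is_a parent)
.sara_backbone <- function() {
  list(
    phenotypic_abnormality = character(),
    abnormality_of_the_nervous_system = "phenotypic_abnormality",
    abnormality_of_nervous_system_physiology = "abnormality_of_the_nervous_system",
    abnormality_of_movement = "abnormality_of_nervous_system_physiology",
    nystagmus = "abnormality_of_nervous_system_physiology",
    incoordination = "abnormality_of_movement",
    gait_disturbance = "abnormality_of_movement",
    tremor = "abnormality_of_movement",
    postural_instability = "abnormality_of_movement",
    ataxia = "incoordination",
    dysmetria = "incoordination",
    cerebellar_ataxia = "ataxia",
    truncal_ataxia = "cerebellar_ataxia",
    appendicular_ataxia = "cerebellar_ataxia",
    gait_ataxia = c("truncal_ataxia", "gait_disturbance"),
    abasia = "gait_ataxia",
    titubation = "truncal_ataxia",
    ataxic_postural_instability = c("truncal_ataxia", "postural_instability"),
    standing_instability = "ataxic_postural_instability",
    astasia = "standing_instability",
    sitting_instability = "ataxic_postural_instability",
    limb_dysmetria = c("dysmetria", "appendicular_ataxia"),
    upper_limb_dysmetria = "limb_dysmetria",
    lower_limb_dysmetria = "limb_dysmetria",
    intention_tremor = c("tremor", "appendicular_ataxia"),
    dysdiadochokinesis = "appendicular_ataxia",
    abnormality_of_speech_or_vocalization = "abnormality_of_the_nervous_system",
    dysarthria = "abnormality_of_speech_or_vocalization",
    scanning_speech = "dysarthria",
    anarthria = "dysarthria"
  )
}

# classes carrying the five generated severity subclasses: the eight
# item-bound classes, the cluster-level superclasses, and their graded
# backbone parents
.sara_graded_classes <- function() {
  c("gait_ataxia", "standing_instability", "sitting_instability",
    "ataxic_postural_instability", "truncal_ataxia", "titubation",
    "dysarthria", "appendicular_ataxia", "limb_dysmetria",
    "upper_limb_dysmetria", "lower_limb_dysmetria", "intention_tremor",
    "dysdiadochokinesis", "cerebellar_ataxia", "dysmetria", "tremor")
}

#' The scaled-down SARA phenotype ontology
#'
#' Constructs the ontology module used by the default interpretation
#' pipeline: a cerebellar-phenotype is_a backbone under a single
#' `phenotypic_abnormality` root, extended with the terminal classes anchored
#' to maximal item scores (`abasia`, `astasia`, `anarthria`) and, for every
#' severity-graded class, five generated severity subclasses
#' (`borderline_...` through `profound_...`).  The result has 109 subclasses
#' of the root.
#'
#' The same ontology ships as a plain-text OBO fixture at
#' `system.file("extdata", "sara_phenotype_synthetic.obo",
#' package = "sarainterp")`; it is a synthetic reconstruction of the
#' published scaled-down Human Phenotype Ontology module (which is not
#' redistributable here), matching its published class count.
#'
#' @return a [phenotype_ontology()] with 110 classes (root plus 109
#'   subclasses).
#' @export
sara_ontology <- function() {
  backbone <- .sara_backbone()
  labels <- gsub("_", " ", names(backbone))
  classes <- Map(onto_class, id = names(backbone), label = labels,
                 parents = backbone)
  ont <- phenotype_ontology(unname(classes), root = "phenotypic_abnormality")
  for (base in .sara_graded_classes()) {
    ont <- add_severity_subclasses(ont, base, SEVERITY_LEVELS)
  }
  ont
}

#' Path to the packaged synthetic SARA ontology fixture
#' @return file path of the OBO fixture inside the installed package.
#' @export
sara_ontology_path <- function() {
  system.file("extdata", "sara_phenotype_synthetic.obo",
              package = "sarainterp", mustWork = TRUE)
}
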