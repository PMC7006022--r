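# Shared constants: the affective space is [0, 100]^3 (negativity,
# positivity, arousal); the study design has two induction groups and two
# face-valence categories; questionnaire instruments are modeled as totals.

RATING_MAX <- 100
MAX_DISTANCE <- RATING_MAX * sqrt(3)

DIMENSIONS <- c("negativity", "positivity", "arousal")
GROUPS <- c("negative_induction", "positive_induction")
VALENCES <- c("happy", "angry")
INSTRUMENTS <- c("ECS", "IRI", "BES", "QPC")
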