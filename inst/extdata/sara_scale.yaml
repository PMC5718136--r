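# SARA content model: the eight items of the Scale for the Assessment and
# Rating of Ataxia, their score ranges, cluster organization and phenotype
# ontology bindings.  The four limb items are scored bilaterally; the mean
# of both sides enters the total, so the maximum total is
# 8 + 6 + 4 + 6 + 4*4 = 40.
name: SARA
version: "1.0"
items:
  - id: gait
    label: Gait
    min: 0
    max: 8
    bilateral: false
    binding: gait_ataxia
    cluster: gait_and_balance
  - id: stance
    label: Stance
    min: 0
    max: 6
    bilateral: false
    binding: standing_instability
    cluster: gait_and_balance
  - id: sitting
    label: Sitting
    min: 0
    max: 4
    bilateral: false
    binding: sitting_instability
    cluster: gait_and_balance
  - id: speech
    label: Speech disturbance
    min: 0
    max: 6
    bilateral: false
    binding: dysarthria
    cluster: speech_disturbance
  - id: finger_chase
    label: Finger chase
    min: 0
    max: 4
    bilateral: true
    binding: limb_dysmetria
    cluster: limb_coordination
  - id: nose_finger
    label: Nose-finger test
    min: 0
    max: 4
    bilateral: true
    binding: intention_tremor
    cluster: limb_coordination
  - id: alternating_hand
    label: Fast alternating hand movements
    min: 0
    max: 4
    bilateral: true
    binding: dysdiadochokinesis
    cluster: limb_coordination
  - id: heel_shin
    label: Heel-shin slide
    min: 0
    max: 4
    bilateral: true
    binding: lower_limb_dysmetria
    cluster: limb_coordination
clusters:
  gait_and_balance: truncal_ataxia
  speech_disturbance: dysarthria
  limb_coordination: appendicular_ataxia
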