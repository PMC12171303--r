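## Input requirements
You are given {n_models} anonymized model responses, each predicting whether
the following two drugs interact.
Drug 1: {name_a} (SMILES: {smiles_a})
Drug 2: {name_b} (SMILES: {smiles_b})

## Prediction task
Assess each prediction and its explanation on four criteria: scientific
accuracy, clarity and coherence, evidence support, and relevance. Score each
criterion on a scale from one to five, then assign an overall score from one
to five. Report your scores exactly in this format, one line per entry:
Model <i> - scientific accuracy: <score>
Model <i> - clarity and coherence: <score>
Model <i> - evidence support: <score>
Model <i> - relevance: <score>
Model <i> - overall: <score>

## Consideration factors
Judge scientific accuracy against established pharmacology; clarity and
coherence by the structure of the argument; evidence support by the
specificity of the cited mechanisms or data; relevance by how directly the
explanation addresses the queried drug pair.

## Worked scoring examples
High-quality evaluation: a response that names a concrete, pharmacologically
plausible mechanism (for example, competition for the same metabolizing
enzyme) and ties it to the queried pair deserves high scores across all
criteria, e.g. scientific accuracy 5, clarity and coherence 5, evidence
support 4, relevance 5, overall 5.
Low-quality evaluation: a response that asserts a verdict with a vague or
generic justification untethered to the queried drugs deserves low scores,
e.g. scientific accuracy 2, clarity and coherence 3, evidence support 1,
relevance 2, overall 2.

## Model responses
{model_blocks}
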