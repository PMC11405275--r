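Your response could not be interpreted. Please use the format "Action: <tool>" with "Action Input: <details>", or state your "Final Diagnosis:" and "Treatment:".
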