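You have gathered enough information. Please now state your conclusion using exactly this format:

Final Diagnosis: <the single most likely diagnosis>
Treatment: <your treatment plan for that diagnosis>
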