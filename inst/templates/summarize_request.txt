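The conversation is getting long. Please summarize the following piece of information you received earlier, keeping every clinically relevant finding and omitting nothing that could change the diagnosis:

{content}
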