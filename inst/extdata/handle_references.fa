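>AsCas12a canonical mature crRNA 5' handle (literature sequence; editable, user-overridable)
UAAUUUCUACUCUUGUAGAU
>FnCas12a canonical mature crRNA 5' handle (literature sequence; editable, user-overridable)
AAUUUCUACUGUUGUAGAU
>LbCas12a canonical mature crRNA 5' handle (literature sequence; editable, user-overridable)
UAAUUUCUACUAAGUGUAGAU
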