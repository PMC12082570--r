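# Acute pancreatitis query — narrow/broad preferred-term scopes.
# Illustrative, editable subset of PTs; NOT the licensed MedDRA SMQ content.
# One preferred term per line; '#' starts a comment.
[narrow]
Pancreatitis acute
Pancreatitis
Pancreatitis haemorrhagic
Pancreatitis necrotising
Oedematous pancreatitis
Ischaemic pancreatitis
[broad]
Lipase increased
Amylase increased
Pancreatic enzymes increased
Abdominal pain upper
Pancreatic necrosis
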