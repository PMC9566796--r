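id,group,intensity,description
S1,S,1,Dissemination of health knowledge unconstrained by time and place
S2,S,2,Varied and accessible content presentation formats
S3,S,4,Audiences flexibly become disseminators within the communication chain
S4,S,6,Algorithmic user profiling delivers precisely targeted content
W1,W,-2,No pre-qualification or post-hoc content review weakens creator responsibility
W2,W,-5,Uneven media literacy across audience age groups
W3,W,-1,Weak personal-information protection and spam erode trust
O1,O,4,National policy support for internet-plus-health development
O2,O,3,Active academic interest in sport-medicine-media integration
O3,O,6,Pandemic-era surge in health aspirations and new-media use
O4,O,2,Rapid platform growth supplies the user base for health content
T1,T,-3,Malicious health marketing driven by commercial capital
T2,T,-2,Uneven regional development widens the health-perception divide
T3,T,-6,Audiences treating media content as a substitute for medical care
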