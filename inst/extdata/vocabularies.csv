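vocabulary,token
locations,head
locations,neck
locations,jaw
locations,shoulders
locations,chest
locations,back
locations,lower back
locations,abdomen
locations,hips
locations,buttocks
locations,groin
locations,upper arm
locations,elbow
locations,forearm
locations,wrist
locations,hand
locations,fingers
locations,thigh
locations,knee
locations,shin
locations,calf
locations,ankle
locations,foot
locations,toes
symptoms,dizziness
symptoms,fever
symptoms,nausea
symptoms,fatigue
symptoms,anxiety
symptoms,depression
symptoms,insomnia
symptoms,headache
symptoms,weakness
symptoms,vomiting
symptoms,sweating
symptoms,irritability
symptoms,poor appetite
symptoms,memory problems
symptoms,ringing ears
symptoms,blurred vision
symptoms,restlessness
symptoms,chills
symptoms,muscle spasms
symptoms,difficulty concentrating
characteristics,burning
characteristics,cramping
characteristics,numbness
characteristics,pins and needles or tingling
characteristics,electric shocks
characteristics,aching
characteristics,stabbing
characteristics,throbbing
characteristics,shooting
characteristics,dull
characteristics,sharp
characteristics,tender
characteristics,pressure
environments,home
environments,work
environments,school
environments,outdoors
environments,in transit
environments,public place
environments,gym
aggravating,sitting
aggravating,standing
aggravating,walking
aggravating,exercise
aggravating,lifting
aggravating,bending
aggravating,stress
aggravating,negative mood
aggravating,light touch or clothing
aggravating,cold weather
aggravating,hot weather
aggravating,lack of sleep
aggravating,driving
aggravating,housework
aggravating,working at computer
alleviating,rest
alleviating,sleep
alleviating,heat
alleviating,ice
alleviating,stretching
alleviating,massage
alleviating,medication
alleviating,meditation
alleviating,distraction
alleviating,walking
alleviating,lying down
alleviating,hot bath
alleviating,music
alleviating,deep breathing
ineffective,rest
ineffective,sleep
ineffective,heat
ineffective,ice
ineffective,stretching
ineffective,massage
ineffective,medication
ineffective,meditation
ineffective,distraction
ineffective,exercise
ineffective,lying down
ineffective,hot bath
ineffective,positive thinking
ineffective,physiotherapy
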